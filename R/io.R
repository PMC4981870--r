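#' Read a gene annotation set
#'
#' Reads gene-to-term annotations from either GMT (`term<TAB>description<TAB>
#' gene1<TAB>gene2...`, one term per line) or a two-column TSV
#' (`gene<TAB>term`, one annotation per line). The result is a long tibble
#' with one row per (term, gene) annotation, the shape every downstream
#' function (gold-standard construction, function prediction, benchmarking)
#' consumes. GMT descriptions are kept in a `term_meta` attribute.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"gmt"`, or `"two-column"`.
#' @return A tibble with columns `term`, `gene`. Attribute `term_meta` is a
#'   tibble `(term, name)` when the source was GMT.
#' @export
read_annotation_set <- function(path, format = c("auto", "gmt", "two-column")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("annotation file is empty: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "two-column"
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gmt") {
    bad <- which(lengths(fields) < 3L)
    if (length(bad) > 0L) {
      abort(sprintf("malformed GMT line %d in %s: need term, description, >=1 gene",
                    bad[1L], path))
    }
    ann <- purrr::map_dfr(fields, function(f) {
      tibble(term = f[[1L]], gene = f[-(1:2)])
    })
    meta <- tibble(
      term = purrr::map_chr(fields, 1L),
      name = purrr::map_chr(fields, 2L)
    )
  } else {
    bad <- which(lengths(fields) != 2L)
    if (length(bad) > 0L) {
      abort(sprintf("malformed two-column line %d in %s: need gene<TAB>term",
                    bad[1L], path))
    }
    ann <- tibble(
      gene = purrr::map_chr(fields, 1L),
      term = purrr::map_chr(fields, 2L)
    )
    meta <- NULL
  }
  if (any(ann$gene == "" | grepl("[[:space:]]", ann$gene))) {
    abort(sprintf("invalid gene identifier (empty or whitespace) in %s", path))
  }
  ann <- distinct(ann, .data$term, .data$gene) %>% select("term", "gene")
  if (!is.null(meta)) attr(ann, "term_meta") <- distinct(meta)
  ann
}

#' Write an annotation set as GMT
#'
#' @param ann Tibble with columns `term`, `gene`.
#' @param path Output path.
#' @param descriptions Optional named character vector of term descriptions;
#'   defaults to the term id itself.
#' @return `path`, invisibly.
#' @export
write_annotation_gmt <- function(ann, path, descriptions = NULL) {
  by_term <- split(ann$gene, ann$term)
  lines <- vapply(names(by_term), function(tm) {
    desc <- if (!is.null(descriptions) && tm %in% names(descriptions)) {
      descriptions[[tm]]
    } else {
      tm
    }
    paste(c(tm, desc, sort(unique(by_term[[tm]]))), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# 6 significant digits: stable, diff-friendly serialization of edge weights
.fmt_weight <- function(w) formatC(w, digits = 6L, format = "g")

#' Read and write weighted edge lists
#'
#' The on-disk form of component and integrated networks: a half-matrix TSV
#' with header `gene_a  gene_b  weight`, each unordered pair exactly once.
#' Weights are serialized with 6 significant digits. `read_edge_list()`
#' rejects self-loops, non-numeric weights and duplicate unordered pairs;
#' with `tolerant = TRUE`, symmetric duplicates carrying identical weights
#' are collapsed instead of rejected.
#'
#' @param path File path.
#' @param tolerant Collapse symmetric duplicate rows with equal weights?
#' @return `read_edge_list()`: tibble `(gene_a, gene_b, weight)` in canonical
#'   pair order. `write_edge_list()`: `path`, invisibly.
#' @export
read_edge_list <- function(path, tolerant = FALSE) {
  if (!file.exists(path)) abort(sprintf("edge list not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_a = readr::col_character(),
    gene_b = readr::col_character(),
    weight = readr::col_character()
  ), progress = FALSE)
  w <- suppressWarnings(as.numeric(df$weight))
  if (anyNA(w)) {
    abort(sprintf("non-numeric weight at data row %d of %s",
                  which(is.na(w))[1L], path))
  }
  df$weight <- w
  net <- canonical_pairs(df)
  key <- .pair_key(net$gene_a, net$gene_b)
  if (anyDuplicated(key)) {
    if (tolerant) {
      grp <- split(net$weight, key)
      incons <- names(grp)[vapply(grp, function(x) length(unique(x)) > 1L, logical(1L))]
      if (length(incons) > 0L) {
        abort(sprintf("duplicate pair with conflicting weights in %s: %s",
                      path, gsub("\t", "/", incons[[1L]])))
      }
      net <- net[!duplicated(key), ]
    } else {
      dup <- key[duplicated(key)][1L]
      abort(sprintf("duplicate unordered pair in %s: %s", path,
                    gsub("\t", "/", dup)))
    }
  }
  arrange(net, .data$gene_a, .data$gene_b)
}

#' @param net Edge table with columns `gene_a`, `gene_b` and a weight column
#'   (one of `ws`, `lls`, `weight`, `score`).
#' @rdname read_edge_list
#' @export
write_edge_list <- function(net, path) {
  .check_edges(net)
  wc <- .weight_col(net)
  net <- canonical_pairs(net) %>% arrange(.data$gene_a, .data$gene_b)
  lines <- c("gene_a\tgene_b\tweight",
             paste(net$gene_a, net$gene_b, .fmt_weight(net[[wc]]), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network in SIF format
#'
#' Simple Interaction Format as consumed by Cytoscape: one line per edge,
#' `gene_a<TAB>relation<TAB>gene_b`, each unordered edge written once. Edge
#' weights are not representable in SIF and are dropped.
#'
#' @param net Edge table (`gene_a`, `gene_b`, ...).
#' @param path Output path.
#' @param relation Relation label, default `"cofunction"`.
#' @return `path`, invisibly. An empty network writes an empty file with a
#'   warning.
#' @export
write_sif <- function(net, path, relation = "cofunction") {
  .check_edges(net)
  if (nrow(net) == 0L) {
    warn("writing SIF for an empty network")
    writeLines(character(), path)
    return(invisible(path))
  }
  net <- canonical_pairs(net) %>%
    distinct(.data$gene_a, .data$gene_b) %>%
    arrange(.data$gene_a, .data$gene_b)
  writeLines(paste(net$gene_a, relation, net$gene_b, sep = "\t"), path)
  invisible(path)
}

#' @param path Path to a SIF file.
#' @rdname write_sif
#' @return `read_sif()`: tibble `(gene_a, gene_b, relation)`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) abort(sprintf("SIF file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(gene_a = character(), gene_b = character(), relation = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed SIF line %d in %s", bad[1L], path))
  }
  canonical_pairs(tibble(
    gene_a = purrr::map_chr(fields, 1L),
    relation = purrr::map_chr(fields, 2L),
    gene_b = purrr::map_chr(fields, 3L)
  )) %>%
    select("gene_a", "gene_b", "relation") %>%
    distinct() %>%
    arrange(.data$gene_a, .data$gene_b)
}

#' Read/write a genes-by-samples numeric matrix
#'
#' TSV with a header of sample (or profile-column) ids and gene ids in the
#' first column. Used for both expression matrices and profile matrices.
#'
#' @param path File path.
#' @return A numeric matrix with gene row names.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("matrix file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene row '%s' in %s", genes[duplicated(genes)][1L], path))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("non-numeric values in %s", path))
  rownames(m) <- genes
  m
}

#' @param m Numeric matrix with gene row names.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  lines <- c(
    paste(c("gene", colnames(m)), collapse = "\t"),
    paste(rownames(m),
          apply(df, 1L, function(r) paste(.fmt_weight(as.numeric(r)), collapse = "\t")),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-order table
#'
#' TSV with columns `genome`, `gene`, `contig`, `index` describing the
#' position of each gene (or ortholog group) along each genome's contigs;
#' the input of the gene-neighborhood evidence scorers.
#'
#' @param path File path.
#' @return Tibble `(genome, gene, contig, index)`.
#' @export
read_gene_orders <- function(path) {
  if (!file.exists(path)) abort(sprintf("gene-order file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    genome = readr::col_character(), gene = readr::col_character(),
    contig = readr::col_character(), index = readr::col_integer()
  ), progress = FALSE)
  dup <- df %>%
    count(.data$genome, .data$contig, .data$index) %>%
    filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate position index %d on %s/%s in %s",
                  dup$index[[1L]], dup$genome[[1L]], dup$contig[[1L]], path))
  }
  df
}

#' Read a cross-species similarity table
#'
#' TSV with columns `query`, `subject`, `direction`, `score`. Directions are
#' `AB`/`BA` for the two cross-species search directions and `AA`/`BB` for
#' within-species similarities (used by InParanoid-style clustering).
#'
#' @param path File path.
#' @return Tibble `(query, subject, direction, score)`.
#' @export
read_similarity_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("similarity file not found: %s", path))
  df <- readr::read_tsv(path, col_types = readr::cols(
    query = readr::col_character(), subject = readr::col_character(),
    direction = readr::col_character(), score = readr::col_double()
  ), progress = FALSE)
  ok <- df$direction %in% c("AB", "BA", "AA", "BB")
  if (!all(ok)) {
    abort(sprintf("invalid direction '%s' in %s (expected AB/BA/AA/BB)",
                  df$direction[!ok][1L], path))
  }
  if (any(df$score < 0)) abort(sprintf("negative similarity score in %s", path))
  df
}
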