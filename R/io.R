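# Readers and writers for the plain-text interchange formats:
# expression TSV (features x samples), labels TSV, probe-level TSV,
# annotation TSV and GMT gene-set collections.

#' Write an expression matrix as TSV
#'
#' Rows are features, columns samples; first column holds the feature id.
#' @param expr numeric matrix, features x samples.
#' @param path output file.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expr_matrix(expr)
  df <- data.frame(feature_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  check_expr_matrix(m)
}

#' Write / read sample labels (two-column TSV: sample_id, class AR/NR)
#' @param labels named AR/NR vector.
#' @param path file path.
#' @export
write_labels_tsv <- function(labels, path) {
  labels <- check_labels(labels)
  utils::write.table(
    data.frame(sample_id = names(labels), class = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_tsv
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_labels(stats::setNames(df$class, df$sample_id))
}

#' Write / read probe-level data
#'
#' Long-by-block TSV with columns probeset_id, probe_id, then one column per
#' array.
#' @param probes a probe collection as produced by [simulate_cohort()].
#' @param path file path.
#' @export
write_probe_level_tsv <- function(probes, path) {
  rows <- lapply(names(probes$blocks), function(ps) {
    b <- probes$blocks[[ps]]
    data.frame(probeset_id = ps, probe_id = rownames(b), b,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_level_tsv
#' @export
read_probe_level_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  arrays <- setdiff(colnames(df), c("probeset_id", "probe_id"))
  blocks <- lapply(split(df, factor(df$probeset_id, unique(df$probeset_id))),
                   function(d) {
                     m <- as.matrix(d[, arrays, drop = FALSE])
                     rownames(m) <- d$probe_id
                     m
                   })
  structure(list(blocks = blocks, arrays = arrays),
            class = "probe_collection")
}

#' Write / read feature annotation (feature_id, gene_symbol, gene_title)
#' @param annotation annotation data frame.
#' @param path file path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read gene sets in GMT format
#'
#' One record per line: name, description, tab-separated members.
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional named descriptions (defaults to the set name).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
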