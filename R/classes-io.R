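#' Array design
#'
#' Describes the layout of an experiment: which biological condition and
#' which replicate each array (column of an intensity or expression matrix)
#' belongs to. The pair (condition, replicate) must be unique, so the design
#' realises the usual condition index \eqn{j} (or \eqn{c}) and replicate
#' index \eqn{i}, with \eqn{R_j} replicates under condition \eqn{j}.
#'
#' @param array_ids character vector of unique array identifiers.
#' @param condition character/factor label per array; every condition must
#'   have at least one array.
#' @param replicate integer replicate index per array.
#' @return An object of class `array_design`: a data.frame with columns
#'   `array_id`, `condition`, `replicate`.
#' @export
array_design <- function(array_ids, condition, replicate) {
  array_ids <- as.character(array_ids)
  condition <- as.character(condition)
  replicate <- as.integer(replicate)
  if (length(array_ids) == 0L)
    stop_schema("design must contain at least one array")
  if (length(condition) != length(array_ids) ||
      length(replicate) != length(array_ids))
    stop_schema("design columns must have equal length")
  if (anyDuplicated(array_ids))
    stop_schema("array ids must be unique")
  key <- paste(condition, replicate, sep = "\r")
  if (anyDuplicated(key))
    stop_schema("(condition, replicate) pairs must be unique")
  d <- data.frame(array_id = array_ids, condition = condition,
                  replicate = replicate, stringsAsFactors = FALSE)
  class(d) <- c("array_design", "data.frame")
  d
}

read_array_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("array_id", "condition", "replicate")
  if (!all(need %in% names(d)))
    stop_schema("design file must have columns: %s", paste(need, collapse = ", "))
  array_design(d$array_id, d$condition, d$replicate)
}

#' Probe intensity panel
#'
#' A matrix of strictly positive raw probe intensities (rows = probes,
#' columns = arrays) together with the array design. Positivity is required
#' because the summarisation models place gamma distributions on the
#' intensities, whose support is (0, Inf).
#'
#' @param intensities numeric matrix, probes x arrays, strictly positive,
#'   with rownames giving unique probe ids.
#' @param design an [array_design] whose rows match the matrix columns.
#' @return An object of class `probe_panel` with elements `intensities`,
#'   `probe_ids`, `design`.
#' @export
probe_panel <- function(intensities, design) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop_schema("intensities must be a numeric matrix")
  if (is.null(rownames(intensities)))
    stop_schema("intensity matrix must have probe ids as rownames")
  if (anyDuplicated(rownames(intensities)))
    stop_schema("probe ids must be unique")
  if (!inherits(design, "array_design")) stop_schema("design must be an array_design")
  if (ncol(intensities) != nrow(design))
    stop_schema("intensity matrix has %d columns but design has %d rows",
                ncol(intensities), nrow(design))
  if (!is.null(colnames(intensities)) &&
      !identical(colnames(intensities), design$array_id))
    stop_schema("intensity column names do not match design array ids")
  colnames(intensities) <- design$array_id
  bad <- !is.finite(intensities) | intensities <= 0
  if (any(bad)) {
    probe <- rownames(intensities)[which(rowSums(bad) > 0)[1L]]
    stop_value("non-positive or missing intensity for probe '%s' (gamma support requires > 0)",
               probe)
  }
  structure(list(intensities = intensities,
                 probe_ids = rownames(intensities),
                 design = design),
            class = "probe_panel")
}

#' Read a probe panel from TSV files
#'
#' The intensity file is tab-separated with a `probe_id` column and one
#' column per array; the design file has columns `array_id`, `condition`,
#' `replicate`. Array sets must match exactly.
#'
#' @param intensity_path,design_path paths to the two TSV files.
#' @return A validated [probe_panel].
#' @export
read_probe_panel <- function(intensity_path, design_path) {
  design <- read_array_design(design_path)
  x <- utils::read.delim(intensity_path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"probe_id" %in% names(x))
    stop_schema("intensity file must have a 'probe_id' column")
  arrays <- setdiff(names(x), "probe_id")
  if (!setequal(arrays, design$array_id))
    stop_schema("arrays in intensity file {%s} do not match design {%s}",
                paste(arrays, collapse = ","),
                paste(design$array_id, collapse = ","))
  m <- as.matrix(x[, design$array_id, drop = FALSE])
  rownames(m) <- x$probe_id
  storage.mode(m) <- "double"
  probe_panel(m, design)
}

#' @rdname read_probe_panel
#' @param panel a [probe_panel] to write.
#' @export
write_probe_panel <- function(panel, intensity_path, design_path = NULL) {
  df <- data.frame(probe_id = panel$probe_ids,
                   panel$intensities, check.names = FALSE)
  utils::write.table(df, intensity_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(design_path))
    utils::write.table(panel$design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(panel)
}

#' Probe-to-transcript-to-gene mapping table
#'
#' Many-to-many links between probes and transcripts (isoforms), plus the
#' transcript-to-gene assignment. A probe may map to several transcripts,
#' possibly of different genes; each transcript belongs to exactly one gene.
#' For gene \eqn{g} and probe \eqn{j} the set M(g, j) is the set of isoforms
#' of \eqn{g} whose sequence contains probe \eqn{j}; a probe's intensity is
#' modelled as the summed contribution of its mapped isoforms.
#'
#' @param df data.frame with columns `probe_id`, `transcript_id`, `gene_id`.
#' @return An object of class `mapping_table`.
#' @export
mapping_table <- function(df) {
  need <- c("probe_id", "transcript_id", "gene_id")
  if (!all(need %in% names(df)))
    stop_schema("mapping must have columns: %s", paste(need, collapse = ", "))
  df <- unique(df[, need])
  df[] <- lapply(df, as.character)
  tg <- unique(df[, c("transcript_id", "gene_id")])
  dup <- tg$transcript_id[duplicated(tg$transcript_id)]
  if (length(dup))
    stop_consistency("transcript '%s' is assigned to more than one gene", dup[1L])
  structure(list(links = df,
                 transcript_gene = stats::setNames(tg$gene_id, tg$transcript_id)),
            class = "mapping_table")
}

#' @export
#' @rdname mapping_table
#' @param path TSV file with columns `probe_id`, `transcript_id`, `gene_id`.
read_mapping_table <- function(path) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    warning("empty mapping table read from '", path, "'")
    df <- data.frame(probe_id = character(), transcript_id = character(),
                     gene_id = character(), stringsAsFactors = FALSE)
  }
  mapping_table(df)
}

genes_of <- function(mapping) unique(mapping$links$gene_id)

# M(g, j) for all probes of gene g: a named list probe_id -> character vector
# of the gene's transcripts containing that probe.
mapping_sets <- function(mapping, gene_id) {
  l <- mapping$links[mapping$links$gene_id == gene_id, , drop = FALSE]
  if (nrow(l) == 0L)
    stop_consistency("gene '%s' has no mapped probes", gene_id)
  split(l$transcript_id, l$probe_id)
}

#' Expression result with measurement error
#'
#' The interchange container between summarisation and downstream analysis:
#' for every target (gene, transcript, or probe-set) and array, a mean log2
#' expression and a standard deviation (the measurement error of that value,
#' also on the log2 scale).
#'
#' @param mean numeric matrix targets x arrays of log2 expression means,
#'   with target ids as rownames.
#' @param sd numeric matrix of the same shape, strictly positive.
#' @param design an [array_design] matching the columns.
#' @param level one of "gene", "transcript", "probeset".
#' @return An object of class `expression_result`.
#' @export
expression_result <- function(mean, sd, design, level = c("gene", "transcript", "probeset")) {
  level <- match.arg(level)
  if (!is.matrix(mean) || !is.matrix(sd) || !all(dim(mean) == dim(sd)))
    stop_schema("mean and sd must be numeric matrices of identical shape")
  if (is.null(rownames(mean))) stop_schema("mean matrix needs target ids as rownames")
  if (!inherits(design, "array_design")) stop_schema("design must be an array_design")
  if (ncol(mean) != nrow(design))
    stop_schema("expression matrix has %d columns but design has %d rows",
                ncol(mean), nrow(design))
  if (any(!is.finite(mean))) stop_value("non-finite expression mean")
  if (any(!is.finite(sd) | sd <= 0)) stop_value("expression sd must be finite and > 0")
  colnames(mean) <- colnames(sd) <- design$array_id
  rownames(sd) <- rownames(mean)
  structure(list(mean = mean, sd = sd, design = design, level = level,
                 target_ids = rownames(mean)),
            class = "expression_result")
}

#' Write / read an expression result as TSV
#'
#' Lossless round-trip: one `target_id` column, then paired `<array>_mean`
#' and `<array>_sd` columns per array; the level tag is kept in a
#' `#level:` header comment and the design in a sibling file when given.
#'
#' @param er an [expression_result].
#' @param path output TSV path.
#' @param design_path optional path for the design TSV.
#' @export
write_expression_result <- function(er, path, design_path = NULL) {
  stopifnot(inherits(er, "expression_result"))
  cols <- list(target_id = er$target_ids)
  for (a in er$design$array_id) {
    cols[[paste0(a, "_mean")]] <- er$mean[, a]
    cols[[paste0(a, "_sd")]] <- er$sd[, a]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#level: %s", er$level), con)
  utils::write.table(as.data.frame(cols, check.names = FALSE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(design_path))
    utils::write.table(er$design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(er)
}

#' @rdname write_expression_result
#' @param design an [array_design], or a path to a design TSV; if NULL a
#'   single-condition design is reconstructed from the array names.
#' @export
read_expression_result <- function(path, design = NULL) {
  first <- readLines(path, n = 1L)
  level <- "gene"
  if (startsWith(first, "#level:"))
    level <- trimws(sub("#level:", "", first, fixed = TRUE))
  x <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                         check.names = FALSE)
  if (!"target_id" %in% names(x)) stop_schema("missing 'target_id' column")
  mcols <- grep("_mean$", names(x), value = TRUE)
  arrays <- sub("_mean$", "", mcols)
  scols <- paste0(arrays, "_sd")
  if (!all(scols %in% names(x)))
    stop_schema("missing sd column(s): %s",
                paste(setdiff(scols, names(x)), collapse = ", "))
  if (is.character(design)) design <- read_array_design(design)
  if (is.null(design))
    design <- array_design(arrays, rep("c1", length(arrays)),
                           seq_along(arrays))
  if (!setequal(arrays, design$array_id))
    stop_schema("arrays in expression file do not match design")
  m <- as.matrix(x[, paste0(design$array_id, "_mean"), drop = FALSE])
  s <- as.matrix(x[, paste0(design$array_id, "_sd"), drop = FALSE])
  rownames(m) <- rownames(s) <- x$target_id
  colnames(m) <- colnames(s) <- design$array_id
  expression_result(m, s, design, level)
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("probe_panel: %d probes x %d arrays (%d conditions)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$design$condition))))
  invisible(x)
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("expression_result (%s level): %d targets x %d arrays\n",
              x$level, nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("mapping_table: %d probe-transcript links, %d transcripts, %d genes\n",
              nrow(x$links), length(x$transcript_gene),
              length(unique(x$transcript_gene))))
  invisible(x)
}
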