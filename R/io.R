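# On-disk artifacts. One tabular dialect: tab-separated, UTF-8, header row,
# "." decimal (locale-independent). CSV is accepted behind an explicit flag.

.read_table <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    cdeg_stop(sprintf("file not found: %s", path), "io_error")
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Read a count matrix and its design table
#'
#' The count file is tabular with a header row: first column `gene_id`,
#' remaining columns one per sample. The design file has columns
#' `sample_id` and `condition` (exactly two condition levels).
#'
#' @param path Path to the count table.
#' @param design_path Path to the design table.
#' @param csv Read comma-separated instead of tab-separated input.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, design_path, csv = FALSE) {
  sep <- if (csv) "," else "\t"
  tab <- .read_table(path, sep)
  if (ncol(tab) < 2L) {
    cdeg_stop("count table needs a gene_id column plus >= 1 sample column",
              "validation_error")
  }
  genes <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
    col <- colnames(tab)[-1L][bad]
    row <- which(is.na(suppressWarnings(as.numeric(tab[[bad + 1L]]))))[1L]
    cdeg_stop(sprintf("non-numeric count for gene '%s', sample '%s'",
                      genes[row %||% 1L], col), "validation_error")
  }
  rownames(mat) <- genes
  des <- .read_table(design_path, sep)
  if (!all(c("sample_id", "condition") %in% names(des))) {
    cdeg_stop("design table needs columns sample_id and condition",
              "design_error")
  }
  count_matrix(mat, des[, c("sample_id", "condition")])
}

#' Write a count matrix and design table
#'
#' Inverse of [read_count_matrix()]; `read(write(x))` is the identity.
#'
#' @param x A `count_matrix`.
#' @param path,design_path Output paths.
#' @param csv Write comma-separated output.
#' @return Invisibly, `x`.
#' @export
write_count_matrix <- function(x, path, design_path, csv = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  sep <- if (csv) "," else "\t"
  tab <- data.frame(gene_id = gene_ids(x), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  des <- data.frame(sample_id = sample_ids(x),
                    condition = unname(x$design[sample_ids(x)]))
  utils::write.table(des, design_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read an externally computed DEG table
#'
#' Adapter input for results produced by external differential-expression
#' tools. Expected columns: `gene_id`, `log2fc`, `pvalue`, `padj`. Rows with
#' a missing p-value or adjusted p-value are dropped (a message reports the
#' count); the external tool's own multiple-testing correction is treated as
#' authoritative downstream.
#'
#' @param path Path to the table.
#' @param method_id Label identifying the external method.
#' @param csv Read comma-separated input.
#' @return A data.frame of class `external_deg_table` with attribute
#'   `method_id`.
#' @export
read_deg_table <- function(path, method_id, csv = FALSE) {
  tab <- .read_table(path, if (csv) "," else "\t")
  need <- c("gene_id", "log2fc", "pvalue", "padj")
  if (!all(need %in% names(tab))) {
    cdeg_stop(sprintf("DEG table must have columns %s",
                      paste(need, collapse = ", ")), "validation_error")
  }
  tab <- tab[, need]
  tab$gene_id <- as.character(tab$gene_id)
  if (anyDuplicated(tab$gene_id)) {
    dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
    cdeg_stop(sprintf("duplicate gene rows in DEG table: %s",
                      paste(utils::head(dup, 5), collapse = ", ")),
              "validation_error")
  }
  drop <- is.na(tab$pvalue) | is.na(tab$padj)
  if (any(drop)) {
    message(sprintf("read_deg_table(%s): dropped %d row(s) with missing p-values",
                    method_id, sum(drop)))
    tab <- tab[!drop, , drop = FALSE]
  }
  for (col in c("pvalue", "padj")) {
    out <- tab[[col]] < 0 | tab[[col]] > 1
    if (any(out)) {
      cdeg_stop(sprintf("%s outside [0,1] for gene '%s'",
                        col, tab$gene_id[which(out)[1]]), "validation_error")
    }
  }
  rownames(tab) <- NULL
  structure(tab, method_id = method_id,
            class = c("external_deg_table", "data.frame"))
}

#' Write / read a reference standard
#'
#' The gene-level table has columns `gene_id` and `label` (1 = consensus
#' positive, 0 = remaining universe member); construction provenance (rule,
#' contributing and excluded methods, filter region, sizes) goes to a JSON
#' sidecar at `<path>.provenance.json`.
#'
#' @param rs A `reference_standard` (see [build_reference_standard()]).
#' @param path Output TSV path.
#' @return Invisibly, `rs`.
#' @export
write_reference_standard <- function(rs, path) {
  stopifnot(inherits(rs, "reference_standard"))
  tab <- data.frame(gene_id = rs$universe,
                    label = as.integer(rs$universe %in% rs$positives))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(rule = rs$rule, methods = rs$methods,
               excluded = rs$excluded, region = rs$region,
               n_positive = length(rs$positives),
               n_universe = length(rs$universe))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rs)
}

#' @rdname write_reference_standard
#' @export
read_reference_standard <- function(path) {
  tab <- .read_table(path)
  provp <- paste0(path, ".provenance.json")
  prov <- if (file.exists(provp)) {
    jsonlite::fromJSON(provp, simplifyVector = TRUE)
  } else list()
  region <- prov$region
  if (!is.null(region)) region <- lapply(region, function(v) {
    if (is.character(v)) suppressWarnings(as.numeric(v)) else v
  })
  structure(list(
    rule = prov$rule %||% "unknown",
    methods = as.character(prov$methods %||% character()),
    excluded = prov$excluded,
    positives = tab$gene_id[tab$label == 1L],
    universe = tab$gene_id,
    region = region
  ), class = "reference_standard")
}
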