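#' Read an expression matrix from GCT 1.2
#'
#' GCT 1.2 is a tab-delimited text format with two header lines (`#1.2`, then
#' `<n_genes>\t<n_samples>`) followed by a table whose first two columns are
#' `Name` and `Description`. Values are returned as a numeric genes x samples
#' matrix on the linear stage.
#'
#' @param path path to a `.gct` file.
#' @return numeric matrix with gene ids as rownames and sample ids as
#'   colnames; stage flag set to `"linear"`.
#' @seealso [write_gct()]
#' @export
read_gct <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !startsWith(hdr[1L], "#1.2")) {
    stop("not a GCT 1.2 file (first line must be '#1.2'): ", path)
  }
  dims <- as.integer(strsplit(hdr[2L], "\t", fixed = TRUE)[[1L]][1:2])
  tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L]) {
    stop(sprintf("GCT dimension line says %d x %d but table is %d x %d",
                 dims[1L], dims[2L], nrow(tab), ncol(tab) - 2L))
  }
  x <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(x) <- tab[[1L]]
  storage.mode(x) <- "double"
  set_stage(x, "linear")
}

#' Write an expression matrix as GCT 1.2
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param path output path.
#' @param description optional per-gene description column (defaults to the
#'   gene ids).
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path, description = rownames(x)) {
  check_expr_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  tab <- data.frame(Name = rownames(x), Description = description,
                    x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-attribute table (GTEx v6 dialect)
#'
#' Expects a tab-delimited file with columns `SAMPID`, `SMTSD` (tissue),
#' `GENDER`, `AGE_BIN`, `SMRIN` (RNA integrity number) and `SMAFRZE`
#' (usable flag; the value `"USE"` marks usable samples).
#'
#' @param path path to the attribute file.
#' @return data.frame with columns `sample`, `tissue`, `gender`, `age_bin`,
#'   `rin`, `usable`.
#' @export
read_sample_attributes <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("SAMPID", "SMTSD", "GENDER", "AGE_BIN", "SMRIN", "SMAFRZE")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("attribute file is missing columns: ", paste(miss, collapse = ", "))
  }
  data.frame(
    sample = tab$SAMPID,
    tissue = tab$SMTSD,
    gender = tab$GENDER,
    age_bin = tab$AGE_BIN,
    rin = as.numeric(tab$SMRIN),
    usable = tab$SMAFRZE == "USE",
    stringsAsFactors = FALSE
  )
}

#' Write sample metadata in the GTEx v6 attribute dialect
#'
#' @param meta data.frame with columns `sample`, `tissue`, `gender`,
#'   `age_bin`, `rin`, `usable` (as produced by [generate_cohort()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_attributes <- function(meta, path) {
  tab <- data.frame(
    SAMPID = meta$sample,
    SMTSD = meta$tissue,
    GENDER = meta$gender,
    AGE_BIN = meta$age_bin,
    SMRIN = meta$rin,
    SMAFRZE = ifelse(meta$usable, "USE", "EXCLUDE"),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a perturbation table as CSV
#'
#' The CSV has the instance metadata columns (`instance`, `drug`,
#' `cell_line`, `dose`, `duration`) followed by one column per gene holding
#' linear-scale fold changes.
#'
#' @param pert a `perturbation_table` (see [generate_perturbations()]).
#' @param path file path.
#' @return `path` (writer) or a `perturbation_table` (reader).
#' @export
write_perturbations <- function(pert, path) {
  stopifnot(inherits(pert, "perturbation_table"))
  tab <- cbind(pert$meta, as.data.frame(pert$folds, check.names = FALSE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_perturbations
#' @export
read_perturbations <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("instance", "drug", "cell_line", "dose", "duration")
  miss <- setdiff(meta_cols, names(tab))
  if (length(miss)) {
    stop("perturbation CSV is missing columns: ", paste(miss, collapse = ", "))
  }
  folds <- as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE])
  storage.mode(folds) <- "double"
  rownames(folds) <- tab$instance
  structure(list(meta = tab[meta_cols], folds = folds),
            class = "perturbation_table")
}

#' Write worm survival and position logs as CSV
#'
#' Survival rows are `worm,arm,plate,day,censored`; position rows follow the
#' lifespan-machine `animal_position.csv` layout `plate,timepoint,x,y`.
#'
#' @param worms result of [generate_worm_experiment()].
#' @param survival_path,positions_path output paths.
#' @return invisibly, the two paths.
#' @export
write_worm_experiment <- function(worms, survival_path, positions_path) {
  utils::write.csv(worms$survival, survival_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(worms$positions[, c("plate", "timepoint", "x", "y")],
                   positions_path, row.names = FALSE, quote = FALSE)
  invisible(c(survival_path, positions_path))
}
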