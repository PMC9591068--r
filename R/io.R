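# File formats: delimited DTI tables, binding-site annotation tables, FASTA
# joins, the YAML run configuration, and JSON metric reports.

DTI_REQUIRED_COLUMNS <- c("smiles", "sequence", "label")
DTI_OPTIONAL_COLUMNS <- c("binding_sites", "protein_id", "drug_id", "split",
                          "rule_label")

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a delimited DTI table
#'
#' Tab- or comma-separated with a header; the separator is auto-detected from
#' the header line. Required columns: `smiles`, `sequence`, `label` (0/1).
#' Recognised optional columns: `binding_sites`, `protein_id`, `drug_id`,
#' `split`, `rule_label`. Unknown columns are an error, catching header typos
#' early.
#'
#' @param path File path.
#' @return DTI data frame.
#' @export
read_dti_table <- function(path) {
  if (!file.exists(path)) stop("cannot read DTI table: no such file: ", path)
  df <- utils::read.delim(path, sep = detect_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(DTI_REQUIRED_COLUMNS, names(df))
  if (length(missing_cols))
    stop("DTI table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(df), c(DTI_REQUIRED_COLUMNS, DTI_OPTIONAL_COLUMNS))
  if (length(unknown))
    stop("DTI table has unknown column(s): ", paste(unknown, collapse = ", "))
  if (!all(df$label %in% c(0, 1)))
    stop("DTI table labels must be 0 or 1")
  df$label <- as.integer(df$label)
  df
}

#' Write a DTI table
#'
#' @param dataset DTI data frame.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_dti_table <- function(dataset, path, sep = "\t") {
  # comma-separated output must quote fields: binding_sites contain commas
  utils::write.table(dataset, path, sep = sep, quote = identical(sep, ","),
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a binding-site annotation table
#'
#' Delimited table with columns `protein_id` and `binding_sites`
#' (comma-separated 1-based residue positions).
#'
#' @param path File path.
#' @return Data frame `protein_id`, `binding_sites`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("cannot read annotations: no such file: ", path)
  df <- utils::read.delim(path, sep = detect_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("protein_id", "binding_sites")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("annotation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df[need]
}

#' Attach binding-site annotations to a DTI table
#'
#' Joins on `protein_id`; rows without a matching annotation keep `NA`.
#'
#' @param dataset DTI data frame with a `protein_id` column.
#' @param annotations Data frame from [read_annotations()].
#' @return The dataset with a filled `binding_sites` column.
#' @export
annotate_dataset <- function(dataset, annotations) {
  if (!"protein_id" %in% names(dataset))
    stop("dataset has no protein_id column to join annotations on")
  dataset$binding_sites <-
    annotations$binding_sites[match(dataset$protein_id,
                                    annotations$protein_id)]
  dataset
}

#' Fill protein sequences from a FASTA file
#'
#' Record ids (first whitespace-delimited word of each header) are matched
#' against the dataset's `protein_id` column.
#'
#' @param dataset DTI data frame with a `protein_id` column (its `sequence`
#'   column may be empty).
#' @param fasta_path FASTA file of protein sequences.
#' @return The dataset with `sequence` filled from the FASTA records.
#' @export
fasta_join <- function(dataset, fasta_path) {
  if (!"protein_id" %in% names(dataset))
    stop("dataset has no protein_id column to join FASTA records on")
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("FASTA input requires the Biostrings package")
  aa <- Biostrings::readAAStringSet(fasta_path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  hit <- match(dataset$protein_id, ids)
  if (anyNA(hit))
    stop("FASTA file lacks record(s): ",
         paste(unique(dataset$protein_id[is.na(hit)]), collapse = ", "))
  dataset$sequence <- as.character(aa)[hit]
  dataset
}

#' Run configuration with the reference defaults
#'
#' Defaults: architecture `CA_P`, scheme `fcs_embed`, max lengths 50/545,
#' hidden 384, 4 heads, learning rate 0.001, 50 epochs, batch 128, decision
#' threshold 0.5, top-30 sites, 10,000 permutation iterations, 5 runs.
#'
#' @param ... Named overrides of any default field (unknown names error).
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    arch = "CA_P", scheme = "fcs_embed",
    max_len_drug = 50L, max_len_protein = 545L,
    hidden = 384L, heads = 4L, lr = 0.001, epochs = 50L, batch_size = 128L,
    threshold = 0.5, k = 30L, iterations = 10000L, n_runs = 5L, seed = 1L,
    min_freq = 5L, max_vocab_drug = 2000L, max_vocab_protein = 10000L,
    paths = list()
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  int_fields <- c("max_len_drug", "max_len_protein", "hidden", "heads",
                  "epochs", "batch_size", "k", "iterations", "n_runs", "seed",
                  "min_freq", "max_vocab_drug", "max_vocab_protein")
  cfg[int_fields] <- lapply(cfg[int_fields], as.integer)
  stopifnot(cfg$arch %in% ARCHITECTURES, cfg$scheme %in% ENCODING_SCHEMES)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: no such file: ", path)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s / %s, hidden %d, heads %d, lr %g, %d epochs, seed %d\n",
    x$arch, x$scheme, x$hidden, x$heads, x$lr, x$epochs, x$seed))
  invisible(x)
}

#' Write metrics (or any named numeric list) as JSON
#'
#' @param values Named list or vector of numbers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(values, path) {
  jsonlite::write_json(as.list(values), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON metrics file
#'
#' @param path File path.
#' @return Named list.
#' @export
read_metrics_json <- function(path) {
  if (!file.exists(path)) stop("cannot read metrics: no such file: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
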