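#' Negative base-10 log transform of a molar concentration
#'
#' The modelled response is \eqn{Y = -\log_{10} C} with \eqn{C} the
#' intracellular concentration in mol/L; e.g. 1 mmol/L maps to 3.0.
#'
#' @param concentration Numeric vector of concentrations in mol/L; all values
#'   must be present and strictly positive.
#' @return Numeric vector of \eqn{-\log_{10}} concentrations (dimensionless).
#' @examples
#' neg_log_transform(c(1e-3, 1))   # 3, 0
#' @export
neg_log_transform <- function(concentration) {
  if (!is.numeric(concentration) || length(concentration) == 0L)
    stop("`concentration` must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(concentration))
    stop("missing concentration values cannot be transformed", call. = FALSE)
  if (any(concentration <= 0))
    stop("concentrations must be strictly positive (mol/L)", call. = FALSE)
  -log10(concentration)
}

#' Construct a metabolite dataset
#'
#' Builds the canonical metabolite table: one row per metabolite x organism,
#' with the concentration (mol/L), its negative log transform, and a split
#' label. If `neg_log_c` is absent it is derived from `concentration`; if both
#' are given they must agree to 1e-9.
#'
#' @param metabolite_id Character vector of metabolite keys.
#' @param name Character vector of display names (defaults to the ids).
#' @param organism Character vector of organism labels (e.g. "eco", "sce");
#'   must be non-empty strings.
#' @param concentration Numeric, mol/L, `NA` allowed where `neg_log_c` is given.
#' @param neg_log_c Numeric, `NA` allowed where `concentration` is given.
#' @param split Character, one of "train", "test", "unassigned".
#' @return A `data.frame` of class `metaconc_dataset`.
#' @export
metabolite_dataset <- function(metabolite_id, organism,
                               concentration = NULL, neg_log_c = NULL,
                               name = metabolite_id,
                               split = "unassigned") {
  metabolite_id <- as.character(metabolite_id)
  organism <- as.character(organism)
  n <- length(metabolite_id)
  if (length(organism) != n)
    stop("`metabolite_id` and `organism` lengths differ", call. = FALSE)
  if (any(!nzchar(organism)) || anyNA(organism))
    stop("organism labels must be non-empty strings", call. = FALSE)
  if (anyDuplicated(paste(metabolite_id, organism, sep = "\r")))
    stop("metabolite_id + organism pairs must be unique", call. = FALSE)
  if (is.null(concentration)) concentration <- rep(NA_real_, n)
  if (is.null(neg_log_c)) neg_log_c <- rep(NA_real_, n)
  concentration <- as.numeric(concentration)
  neg_log_c <- as.numeric(neg_log_c)
  if (length(concentration) != n || length(neg_log_c) != n)
    stop("concentration/neg_log_c lengths differ from metabolite_id", call. = FALSE)
  if (any(!is.na(concentration) & concentration <= 0))
    stop("concentrations must be strictly positive where present", call. = FALSE)
  derive <- is.na(neg_log_c) & !is.na(concentration)
  if (any(derive))
    neg_log_c[derive] <- neg_log_transform(concentration[derive])
  both <- !is.na(neg_log_c) & !is.na(concentration)
  if (any(abs(neg_log_c[both] + log10(concentration[both])) > 1e-9))
    stop("neg_log_c inconsistent with -log10(concentration)", call. = FALSE)
  if (any(is.na(neg_log_c) & is.na(concentration)))
    stop("each record needs concentration or neg_log_c", call. = FALSE)
  split <- rep_len(as.character(split), n)
  if (!all(split %in% c("train", "test", "unassigned")))
    stop("split labels must be train/test/unassigned", call. = FALSE)
  out <- data.frame(metabolite_id = metabolite_id,
                    name = rep_len(as.character(name), n),
                    organism = organism,
                    concentration_molar = concentration,
                    neg_log_c = neg_log_c,
                    split = split,
                    stringsAsFactors = FALSE)
  class(out) <- c("metaconc_dataset", "data.frame")
  out
}

#' Read / write the metabolite table (TSV)
#'
#' Columns: metabolite_id, name, organism, concentration_molar, neg_log_c,
#' split. Missing values are written as the literal "NA".
#'
#' @param path File path.
#' @return `read_metabolite_table` returns a `metaconc_dataset`;
#'   `write_metabolite_table` returns `path` invisibly.
#' @export
read_metabolite_table <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("metabolite_id", "organism")
  if (!all(need %in% names(df)))
    stop("metabolite table must have columns metabolite_id and organism", call. = FALSE)
  metabolite_dataset(
    metabolite_id = df$metabolite_id,
    organism = df$organism,
    concentration = if ("concentration_molar" %in% names(df)) df$concentration_molar,
    neg_log_c = if ("neg_log_c" %in% names(df)) df$neg_log_c,
    name = if ("name" %in% names(df)) df$name else df$metabolite_id,
    split = if ("split" %in% names(df)) df$split else "unassigned")
}

#' @rdname read_metabolite_table
#' @param dataset A `metaconc_dataset`.
#' @export
write_metabolite_table <- function(dataset, path) {
  write_tsv_det(as.data.frame(dataset), path)
  invisible(path)
}

#' Random training/test split
#'
#' Assigns exactly `n_train` records to the training set and the remainder to
#' the test set, by a seeded uniform draw without replacement (the study design
#' splits 130 metabolites into 91 train / 39 test).
#'
#' @param dataset A `metaconc_dataset`.
#' @param n_train Number of training records, `0 < n_train < nrow(dataset)`.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return The dataset with its `split` column filled in.
#' @export
split_random <- function(dataset, n_train, seed) {
  n <- nrow(dataset)
  stopifnot_scalar_number(n_train, "n_train")
  if (n_train <= 0 || n_train >= n)
    stop("`n_train` must lie strictly between 0 and the record count", call. = FALSE)
  idx <- with_seed(seed, sample.int(n, n_train))
  dataset$split <- "test"
  dataset$split[idx] <- "train"
  dataset
}

#' Non-overlap training/test split
#'
#' Records sharing a `metabolite_id` (the same compound measured in several
#' organisms) are forced onto the same side, so no metabolite can appear in
#' both the training and the test set. Whole id-groups are assigned greedily
#' by descending group size to the side whose deficit against its target is
#' larger; the seed shuffles the order among equal-sized groups.
#'
#' @inheritParams split_random
#' @param n_train_target Desired training-set size; attained as closely as the
#'   grouping allows.
#' @return The dataset with `split` filled in.
#' @export
split_non_overlap <- function(dataset, n_train_target, seed) {
  n <- nrow(dataset)
  stopifnot_scalar_number(n_train_target, "n_train_target")
  if (n_train_target <= 0 || n_train_target >= n)
    stop("`n_train_target` must lie strictly between 0 and the record count",
         call. = FALSE)
  sizes <- table(dataset$metabolite_id)
  if (max(sizes) > max(n_train_target, n - n_train_target))
    stop("an id-group is larger than both split sides; grouping impossible",
         call. = FALSE)
  ids <- names(sizes)
  ord <- with_seed(seed, {
    perm <- sample.int(length(ids))
    perm[order(-as.integer(sizes)[perm])]  # descending size, seeded tie order
  })
  train_ids <- character(0)
  n_tr <- 0L
  n_te <- 0L
  n_test_target <- n - n_train_target
  for (i in ord) {
    s <- as.integer(sizes[[i]])
    # assign to the side with the larger remaining deficit (ties -> train)
    if ((n_train_target - n_tr) >= (n_test_target - n_te)) {
      train_ids <- c(train_ids, ids[i]); n_tr <- n_tr + s
    } else {
      n_te <- n_te + s
    }
  }
  dataset$split <- ifelse(dataset$metabolite_id %in% train_ids, "train", "test")
  dataset
}

#' Write a JSON run manifest
#'
#' Records seeds, input-file MD5 hashes and record counts so a run can be
#' reproduced bit-for-bit.
#'
#' @param path Output path for the JSON manifest.
#' @param seeds Named list/vector of seeds used.
#' @param files Character vector of input file paths to hash (missing files
#'   are recorded with hash `NA`).
#' @param counts Named list of counts to record.
#' @param extra Named list of further settings worth recording.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seeds = list(), files = character(0),
                               counts = list(), extra = list()) {
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest <- list(package = "metaconc",
                   version = as.character(utils::packageVersion("metaconc")),
                   seeds = seeds, input_hashes = hashes, counts = counts)
  if (length(extra)) manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
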