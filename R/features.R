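#' Read a pathway-membership file
#'
#' Accepts a two-column TSV (`metabolite_id`, `pathway_id`; one row per
#' membership) or a GMT-style file (`pathway<TAB>description<TAB>member...`).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gmt"`.
#' @return A named list: metabolite id -> character vector of pathway keys.
#' @export
read_pathway_membership <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_plain(path)
    if (!all(c("metabolite_id", "pathway_id") %in% names(df)))
      stop("membership file needs metabolite_id and pathway_id columns",
           call. = FALSE)
    split(as.character(df$pathway_id), as.character(df$metabolite_id))
  } else {
    lines <- readLines(path)
    out <- list()
    for (ln in lines[nzchar(lines)]) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) next
      for (m in f[-(1:2)]) out[[m]] <- c(out[[m]], f[1])
    }
    out
  }
}

#' Binary pathway-membership variables
#'
#' One 0/1 column per pathway: 1 if the metabolite participates in that
#' pathway, else 0.
#'
#' @param members Named list mapping metabolite id -> pathway keys.
#' @param pathways Character vector of pathway keys (column set).
#' @param rows Character vector of metabolite ids defining the row order.
#' @return Numeric matrix `length(rows)` x `length(pathways)` with dimnames.
#' @export
pathway_variables <- function(members, pathways, rows) {
  if (length(pathways) == 0L)
    stop("`pathways` must be non-empty", call. = FALSE)
  pathways <- unique(as.character(pathways))
  mat <- matrix(0, nrow = length(rows), ncol = length(pathways),
                dimnames = list(rows, pathways))
  for (i in seq_along(rows)) {
    p <- intersect(members[[rows[i]]], pathways)
    if (length(p)) mat[i, p] <- 1
  }
  mat
}

#' Metabolite Pathways' Feature (MPF) descriptor
#'
#' A single binary column: 1 iff the metabolite participates in at least one
#' of the selected pathways — the element-wise OR of the selected pathway
#' variables.
#'
#' @inheritParams pathway_variables
#' @param selected_pathways Non-empty character vector of retained pathways.
#' @return Numeric 0/1 vector named by `rows`.
#' @export
build_mpf <- function(members, selected_pathways, rows) {
  if (length(selected_pathways) == 0L)
    stop("`selected_pathways` must be non-empty", call. = FALSE)
  pv <- pathway_variables(members, selected_pathways, rows)
  out <- as.numeric(rowSums(pv) > 0)
  names(out) <- rows
  out
}

#' Assemble the full feature matrix
#'
#' Column-binds molecular descriptors, per-record topology descriptors and
#' binary pathway variables into one numeric matrix with a `column_origin`
#' attribute tagging every column as "molecular", "topology", "pathway" or
#' "mpf". Metabolites measured in several organisms share molecular and
#' pathway values but carry organism-specific topology values, so rows are
#' keyed by metabolite x organism.
#'
#' @param dataset A `metaconc_dataset` giving the row order (metabolite x
#'   organism records).
#' @param molecular Numeric matrix/data.frame of molecular descriptors, rows
#'   named by metabolite id. Strict mode (default) rejects missing cells;
#'   lenient mode mean-imputes them with a warning giving the count.
#' @param topology Optional per-organism list of networks (named by organism
#'   label) or a single network applied to all records.
#' @param pathway Optional membership list (see [pathway_variables()]) plus
#'   `pathways`, the pathway universe.
#' @param pathways Character vector of pathway keys (required with `pathway`).
#' @param missing One of `"strict"`, `"impute"`.
#' @return Numeric matrix with rownames `metabolite_id@organism` and attribute
#'   `column_origin`.
#' @export
assemble_features <- function(dataset, molecular, topology = NULL,
                              pathway = NULL, pathways = NULL,
                              missing = c("strict", "impute")) {
  missing <- match.arg(missing)
  molecular <- as.matrix(molecular)
  if (is.null(rownames(molecular)))
    stop("`molecular` must have metabolite ids as rownames", call. = FALSE)
  ids <- dataset$metabolite_id
  if (!all(ids %in% rownames(molecular)))
    stop("molecular descriptors missing for some metabolites", call. = FALSE)
  X <- molecular[ids, , drop = FALSE]
  if (anyNA(X)) {
    if (missing == "strict")
      stop(sprintf("%d missing molecular-descriptor cells (strict mode)",
                   sum(is.na(X))), call. = FALSE)
    n_imp <- sum(is.na(X))
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
    warning(sprintf("mean-imputed %d missing descriptor cells", n_imp),
            call. = FALSE)
  }
  origin <- rep("molecular", ncol(X))
  if (!is.null(topology)) {
    nets <- if (inherits(topology, "igraph"))
      stats::setNames(rep(list(topology), length(unique(dataset$organism))),
                      unique(dataset$organism))
    else topology
    topo <- matrix(0, nrow = nrow(dataset), ncol = 2,
                   dimnames = list(NULL, c("Degree", "Clustering-Coefficient")))
    for (org in unique(dataset$organism)) {
      sel <- dataset$organism == org
      if (is.null(nets[[org]]))
        stop(sprintf("no network supplied for organism '%s'", org), call. = FALSE)
      td <- topology_descriptors(nets[[org]], ids[sel])
      topo[sel, "Degree"] <- td$degree
      topo[sel, "Clustering-Coefficient"] <- td$clustering_coefficient
    }
    X <- cbind(X, topo)
    origin <- c(origin, rep("topology", 2L))
  }
  if (!is.null(pathway)) {
    if (is.null(pathways)) stop("`pathways` required with `pathway`", call. = FALSE)
    pv <- pathway_variables(pathway, pathways, ids)
    rownames(pv) <- NULL
    X <- cbind(X, pv)
    origin <- c(origin, rep("pathway", ncol(pv)))
  }
  if (anyDuplicated(colnames(X)))
    stop("duplicate descriptor names after assembly", call. = FALSE)
  rownames(X) <- paste(ids, dataset$organism, sep = "@")
  attr(X, "column_origin") <- stats::setNames(origin, colnames(X))
  X
}

#' Variance-based descriptor preprocessing
#'
#' Removes descriptors that are constant across the dataset (uninformative;
#' e.g. atom counts for absent atom types) and descriptors whose sample
#' standard deviation (n-1 denominator) falls below `sd_threshold`. Binary
#' pathway columns are additionally dropped when their minority class holds
#' fewer than `pathway_min_minority` records (near-constant membership).
#'
#' @param X Feature matrix from [assemble_features()] (a plain numeric matrix
#'   also works; all columns then count as "molecular").
#' @param sd_threshold Columns with sd below this are dropped (default 0.001).
#' @param pathway_min_minority Minimum minority-class count for binary
#'   pathway columns (default 2).
#' @return A list with `matrix` (filtered, `column_origin` preserved) and
#'   `report`, a list with `removed_constant`, `removed_low_sd`,
#'   `removed_near_constant_pathway`, `kept`, `sd_threshold`.
#' @export
preprocess_features <- function(X, sd_threshold = 0.001,
                                pathway_min_minority = 2L) {
  X <- ensure_origin(X)
  origin <- attr(X, "column_origin")
  sds <- apply(X, 2L, stats::sd)
  rng <- apply(X, 2L, function(v) diff(range(v)))
  constant <- rng == 0
  low_sd <- !constant & sds < sd_threshold
  near_const_pw <- rep(FALSE, ncol(X))
  pw <- origin %in% c("pathway", "mpf")
  if (any(pw)) {
    minority <- pmin(apply(X[, pw, drop = FALSE], 2L, function(v) sum(v != v[1])),
                     apply(X[, pw, drop = FALSE], 2L, function(v) sum(v == v[1])))
    near_const_pw[pw] <- !constant[pw] & !low_sd[pw] &
      minority < pathway_min_minority
  }
  drop <- constant | low_sd | near_const_pw
  if (all(drop))
    stop("preprocessing removed every descriptor", call. = FALSE)
  kept <- X[, !drop, drop = FALSE]
  attr(kept, "column_origin") <- origin[!drop]
  list(matrix = kept,
       report = list(removed_constant = colnames(X)[constant],
                     removed_low_sd = colnames(X)[low_sd],
                     removed_near_constant_pathway = colnames(X)[near_const_pw],
                     kept = colnames(kept),
                     sd_threshold = sd_threshold))
}

ensure_origin <- function(X) {
  X <- as.matrix(X)
  if (is.null(attr(X, "column_origin")))
    attr(X, "column_origin") <- stats::setNames(rep("molecular", ncol(X)),
                                                colnames(X))
  X
}

#' CLogP-binned concentration correlation report
#'
#' Bins metabolites by CLogP (calculated octanol/water partition coefficient)
#' at a fixed bin width, reports each bin's mean CLogP and mean -logC, and the
#' R-squared of the linear fit across bin means. A strong positive fit shows
#' that more polar (more water-soluble) metabolites tend to sit at higher
#' intracellular concentrations.
#'
#' @param dataset A `metaconc_dataset`.
#' @param clogp Numeric vector of CLogP values, either parallel to the dataset
#'   rows or named by metabolite id.
#' @param bin_width Bin width on the CLogP axis (default 0.5).
#' @return A list: `bins` (data.frame bin, n, mean_clogp, mean_neg_log_c) and
#'   `r_squared` of the across-bin linear fit.
#' @export
clogp_bin_report <- function(dataset, clogp, bin_width = 0.5) {
  if (!is.null(names(clogp))) clogp <- clogp[dataset$metabolite_id]
  if (length(clogp) != nrow(dataset) || anyNA(clogp))
    stop("CLogP must be available for every record", call. = FALSE)
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  bin <- floor(clogp / bin_width)
  if (length(unique(bin)) < 3L)
    stop("fewer than 3 non-empty CLogP bins", call. = FALSE)
  sp <- split(data.frame(clogp = clogp, y = dataset$neg_log_c), bin)
  bins <- do.call(rbind, lapply(names(sp), function(b)
    data.frame(bin_lower = as.numeric(b) * bin_width, n = nrow(sp[[b]]),
               mean_clogp = mean(sp[[b]]$clogp),
               mean_neg_log_c = mean(sp[[b]]$y))))
  bins <- bins[order(bins$bin_lower), , drop = FALSE]
  rownames(bins) <- NULL
  # simple-regression identity: fit R^2 = squared correlation of bin means
  list(bins = bins,
       r_squared = stats::cor(bins$mean_clogp, bins$mean_neg_log_c)^2)
}

#' Pathway-deviation summary for the MPF member metabolites
#'
#' For the metabolites belonging to the pathways collapsed into the MPF
#' descriptor, tabulates -logC per organism and CLogP, and reports group means
#' (per organism, NA-excluded) next to the full-dataset means. Members of
#' these non-core pathways typically combine below-average polarity with
#' above-average concentration, which is why the MPF variable carries signal
#' beyond CLogP alone.
#'
#' @param dataset A `metaconc_dataset` (may contain several organisms).
#' @param mpf_members Character vector of member metabolite ids (or names when
#'   `by = "name"`).
#' @param clogp Numeric vector of CLogP values named by metabolite id/name, or
#'   parallel to `mpf_members`.
#' @param by Match members against `"metabolite_id"` (default) or `"name"`.
#' @return A list: `members` (data.frame name plus one -logC column per
#'   organism and `clogp`), `member_means` (named numeric: per-organism mean
#'   -logC, NA-excluded, and mean CLogP), `dataset_means` (mean -logC over all
#'   records and mean CLogP over all metabolites with a CLogP value).
#' @export
pathway_deviation_table <- function(dataset, mpf_members, clogp,
                                    by = c("metabolite_id", "name")) {
  by <- match.arg(by)
  if (length(mpf_members) == 0L)
    stop("`mpf_members` must be non-empty", call. = FALSE)
  orgs <- sort(unique(dataset$organism))
  key <- dataset[[by]]
  if (is.null(names(clogp)))
    names(clogp) <- mpf_members
  tab <- data.frame(member = mpf_members, stringsAsFactors = FALSE)
  for (org in orgs) {
    v <- rep(NA_real_, length(mpf_members))
    sub <- dataset[dataset$organism == org, , drop = FALSE]
    m <- match(mpf_members, sub[[by]])
    v[!is.na(m)] <- sub$neg_log_c[m[!is.na(m)]]
    tab[[paste0("neg_log_c_", org)]] <- v
  }
  tab$clogp <- unname(clogp[mpf_members])
  member_means <- c(
    stats::setNames(vapply(orgs, function(org)
      mean(tab[[paste0("neg_log_c_", org)]], na.rm = TRUE), numeric(1)),
      paste0("mean_neg_log_c_", orgs)),
    mean_clogp = mean(tab$clogp, na.rm = TRUE))
  dataset_means <- c(mean_neg_log_c = mean(dataset$neg_log_c, na.rm = TRUE))
  list(members = tab, member_means = member_means,
       dataset_means = dataset_means)
}
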