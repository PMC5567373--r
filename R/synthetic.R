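#' Synthetic-data generator configuration
#'
#' Defines a complete synthetic study: metabolite records over one or more
#' organisms (with optional cross-organism shared metabolites), correlated
#' Gaussian molecular descriptors, organism-specific random metabolic
#' networks, Bernoulli pathway memberships, and a known sparse generative link
#' \deqn{-logC = b_0 + X\beta + t \cdot CC + o \cdot MPF_{true} + N(0, \sigma)}
#' where \eqn{X\beta} runs over the informative molecular descriptors,
#' \eqn{CC} is the node clustering coefficient, and \eqn{MPF_{true}} marks
#' membership in the designated offset-carrying pathways.
#'
#' Defaults emulate the study conditions this package models: 130 records
#' (93 *E. coli* + 37 *S. cerevisiae*, 15 metabolites measured in both), a
#' ClogP-like polarity descriptor with a positive coefficient, a negative
#' clustering-coefficient effect, a negative offset for members of the
#' MPF-like pathways (higher concentration at lower polarity), an intercept at
#' the overall -logC mean 3.57, and noise sd 0.2 (-logC units).
#'
#' @param organisms Named integer vector: records per organism.
#' @param n_shared Number of metabolite ids present in every organism.
#' @param n_molecular_descriptors Number of molecular descriptor columns
#'   (including the leading `ClogP` column).
#' @param n_pathways Number of pathways in the universe.
#' @param informative Named numeric vector of true coefficients over
#'   descriptor names (must exist among the generated descriptors).
#' @param intercept Baseline -logC.
#' @param topology_effect Coefficient on the clustering coefficient.
#' @param n_mpf_pathways How many pathways carry the MPF offset.
#' @param mpf_offset Additive -logC offset for members of those pathways.
#' @param noise_sd Gaussian noise sd in -logC units (>= 0).
#' @param network_model `"erdos_renyi"` or `"barabasi_albert"`.
#' @param mean_degree Target mean node degree of the generated networks.
#' @param collinearity Mixing weight in \[0, 1) toward a random correlation
#'   structure among molecular descriptors.
#' @param seed Integer seed; everything is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(organisms = c(eco = 93L, sce = 37L),
                             n_shared = 15L,
                             n_molecular_descriptors = 50L,
                             n_pathways = 20L,
                             informative = c(ClogP = 0.4, MD001 = 1.0,
                                             MD002 = -0.8, MD003 = 0.6,
                                             MD004 = -0.5),
                             intercept = 3.57,
                             topology_effect = -0.5,
                             n_mpf_pathways = 3L,
                             mpf_offset = -0.8,
                             noise_sd = 0.2,
                             network_model = c("erdos_renyi", "barabasi_albert"),
                             mean_degree = 4,
                             collinearity = 0.3,
                             seed = 1L) {
  network_model <- match.arg(network_model)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(names(organisms)) || any(!nzchar(names(organisms))))
    stop("`organisms` must be a named count vector", call. = FALSE)
  if (n_shared > 0 && length(organisms) < 2L) n_shared <- 0L
  if (n_shared >= min(organisms) && length(organisms) > 1L)
    stop("`n_shared` must be smaller than every organism's record count",
         call. = FALSE)
  structure(list(organisms = organisms, n_shared = as.integer(n_shared),
                 n_molecular_descriptors = as.integer(n_molecular_descriptors),
                 n_pathways = as.integer(n_pathways),
                 informative = informative, intercept = intercept,
                 topology_effect = topology_effect,
                 n_mpf_pathways = as.integer(n_mpf_pathways),
                 mpf_offset = mpf_offset, noise_sd = noise_sd,
                 network_model = network_model, mean_degree = mean_degree,
                 collinearity = collinearity, seed = as.integer(seed)),
            class = "synthetic_config")
}

descriptor_names <- function(k) {
  c("ClogP", sprintf("MD%03d", seq_len(k - 1L)))
}

#' Generate a complete synthetic study
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_study`:
#'   `dataset` (a `metaconc_dataset`), `molecular` (metabolite x descriptor
#'   matrix), `features` (assembled record-level matrix with
#'   `column_origin`), `networks` (per-organism igraph), `members` (pathway
#'   membership list), `pathways` (pathway universe), `clogp` (named vector),
#'   and `truth` (coefficients, informative names, per-record linear
#'   predictor, analytic mean/variance/R-squared of the signal).
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  dn <- descriptor_names(cfg$n_molecular_descriptors)
  unknown <- setdiff(names(cfg$informative), dn)
  if (length(unknown))
    stop(sprintf("informative set names unknown descriptors: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  orgs <- names(cfg$organisms)
  n_unique <- sum(cfg$organisms) - cfg$n_shared * (length(orgs) - 1L)
  ids <- sprintf("M%04d", seq_len(n_unique))
  with_seed(cfg$seed, {
    # --- assign metabolites to organisms (first n_shared ids go everywhere)
    shared <- ids[seq_len(cfg$n_shared)]
    rest <- setdiff(ids, shared)
    org_ids <- list()
    offset <- 0L
    for (o in orgs) {
      n_own <- cfg$organisms[[o]] - cfg$n_shared
      org_ids[[o]] <- c(shared, rest[seq_len(n_own) + offset])
      offset <- offset + n_own
    }
    # --- correlated molecular descriptors per unique metabolite
    d <- cfg$n_molecular_descriptors
    W <- matrix(stats::rnorm(d * d), d, d)
    R <- stats::cov2cor(crossprod(W) + diag(d))
    Sigma <- (1 - cfg$collinearity) * diag(d) + cfg$collinearity * R
    L <- chol(Sigma)
    molecular <- matrix(stats::rnorm(n_unique * d), n_unique, d) %*% L
    dimnames(molecular) <- list(ids, dn)
    # --- pathway memberships
    pathways <- sprintf("Map%05d", seq_len(cfg$n_pathways))
    rates <- stats::runif(cfg$n_pathways, 0.05, 0.30)
    if (cfg$n_mpf_pathways > 0)
      rates[seq_len(cfg$n_mpf_pathways)] <- 0.05
    member_mat <- matrix(stats::rbinom(n_unique * cfg$n_pathways, 1L,
                                       rep(rates, each = n_unique)),
                         n_unique, cfg$n_pathways,
                         dimnames = list(ids, pathways))
    members <- apply(member_mat, 1L, function(r) pathways[r == 1L],
                     simplify = FALSE)
    mpf_true <- if (cfg$n_mpf_pathways > 0)
      as.numeric(rowSums(member_mat[, seq_len(cfg$n_mpf_pathways),
                                    drop = FALSE]) > 0)
    else rep(0, n_unique)
    names(mpf_true) <- ids
    # --- organism-specific networks over the organism's metabolites
    networks <- lapply(org_ids, function(oid) {
      n_o <- length(oid)
      g <- if (cfg$network_model == "erdos_renyi") {
        p <- min(1, cfg$mean_degree / max(1, n_o - 1))
        igraph::sample_gnp(n_o, p)
      } else {
        igraph::sample_pa(n_o, m = max(1, round(cfg$mean_degree / 2)),
                          directed = FALSE)
      }
      igraph::V(g)$name <- oid
      igraph::simplify(g)
    })
    names(networks) <- orgs
    # --- records and response
    rec_id <- unlist(lapply(orgs, function(o) org_ids[[o]]), use.names = FALSE)
    rec_org <- rep(orgs, times = vapply(org_ids, length, integer(1)))
    cc <- numeric(length(rec_id))
    for (o in orgs) {
      sel <- rec_org == o
      cc[sel] <- topology_descriptors(networks[[o]],
                                      rec_id[sel])$clustering_coefficient
    }
    beta <- stats::setNames(rep(0, d), dn)
    beta[names(cfg$informative)] <- cfg$informative
    linpred <- cfg$intercept +
      as.numeric(molecular[rec_id, , drop = FALSE] %*% beta) +
      cfg$topology_effect * cc + cfg$mpf_offset * mpf_true[rec_id]
    y <- linpred + stats::rnorm(length(linpred), 0, cfg$noise_sd)
    dataset <- metabolite_dataset(metabolite_id = rec_id, organism = rec_org,
                                  neg_log_c = y)
    dataset$concentration_molar <- 10^(-y)
    features <- assemble_features(dataset, molecular, topology = networks,
                                  pathway = members, pathways = pathways)
    sig_var <- stats::var(linpred)
    truth <- list(coefficients = beta,
                  informative = names(cfg$informative),
                  intercept = cfg$intercept,
                  topology_effect = cfg$topology_effect,
                  mpf_offset = cfg$mpf_offset,
                  mpf_pathways = pathways[seq_len(cfg$n_mpf_pathways)],
                  mpf_true = mpf_true,
                  linear_predictor = linpred,
                  analytic_mean = mean(linpred),
                  analytic_signal_variance = sig_var,
                  analytic_r2 = if (sig_var + cfg$noise_sd^2 > 0)
                    sig_var / (sig_var + cfg$noise_sd^2) else NA_real_)
    structure(list(dataset = dataset, molecular = molecular,
                   features = features, networks = networks,
                   members = members, pathways = pathways,
                   clogp = stats::setNames(molecular[, "ClogP"], ids),
                   truth = truth, config = cfg),
              class = "synthetic_study")
  })
}

#' Serialize a synthetic study in the pipeline's input formats
#'
#' Writes the metabolite table (TSV), the molecular-descriptor matrix (CSV,
#' first column `metabolite_id`), one reactant-pair file per organism (TSV
#' with `substrate_id`, `product_id`, `pathway_ids`, `unspecified_residue`)
#' and the pathway-membership file (TSV). Output is byte-identical across
#' reruns of the same study.
#'
#' @param study A `synthetic_study` from [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metabolites = file.path(dir, "metabolites.tsv"),
             descriptors = file.path(dir, "molecular_descriptors.csv"),
             membership = file.path(dir, "pathway_membership.tsv"))
  write_metabolite_table(study$dataset, paths[["metabolites"]])
  md <- data.frame(metabolite_id = rownames(study$molecular),
                   study$molecular, check.names = FALSE)
  con <- file(paths[["descriptors"]], open = "wb")
  writeLines(paste(names(md), collapse = ","), con)
  body <- apply(cbind(md[[1]],
                      format(study$molecular, digits = 15, trim = TRUE,
                             scientific = FALSE)),
                1L, paste, collapse = ",")
  writeLines(body, con)
  close(con)
  mem <- do.call(rbind, lapply(names(study$members), function(id) {
    p <- study$members[[id]]
    if (length(p) == 0L) return(NULL)
    data.frame(metabolite_id = id, pathway_id = p, stringsAsFactors = FALSE)
  }))
  write_tsv_det(mem, paths[["membership"]])
  # one organism pathway is attached per edge so reconstruction keeps them all
  for (o in names(study$networks)) {
    p <- file.path(dir, sprintf("reactant_pairs_%s.tsv", o))
    el <- igraph::as_edgelist(study$networks[[o]], names = TRUE)
    pairs <- data.frame(substrate_id = el[, 1], product_id = el[, 2],
                        pathway_ids = paste0("org_", o),
                        unspecified_residue = 0L, stringsAsFactors = FALSE)
    write_tsv_det(pairs, p)
    paths[[paste0("pairs_", o)]] <- p
  }
  invisible(paths)
}

#' Reference deviation table of the MPF member metabolites
#'
#' The packaged 14-metabolite table of -logC (per organism) and CLogP for the
#' members of the five pathways collapsed into the MPF descriptor, as shipped
#' in `inst/extdata/mpf_member_deviation.tsv`. "NA" marks no data available.
#'
#' @return data.frame with columns `name`, `neg_log_c_eco`, `neg_log_c_sce`,
#'   `clogp` (14 rows).
#' @export
mpf_deviation_fixture <- function() {
  path <- system.file("extdata", "mpf_member_deviation.tsv",
                      package = "metaconc", mustWork = TRUE)
  read_tsv_plain(path)
}
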