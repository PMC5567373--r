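#' Read a reactant-pair table
#'
#' A reactant pair is a substrate-product compound pair extracted from a
#' reaction database; it becomes an undirected edge in the metabolite-centric
#' network. Expected TSV columns: `substrate_id`, `product_id`, `pathway_ids`
#' (semicolon-separated, may be empty) and `unspecified_residue` (0/1). A
#' simple SIF file (`node<TAB>relation<TAB>node`) is also accepted, with
#' pathway/residue information supplied through `sif_pathways`.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param sif_pathways For SIF input, an optional data.frame with columns
#'   `substrate_id`, `product_id`, `pathway_ids`, `unspecified_residue`
#'   merged onto the edges (unmatched edges get no pathways and residue 0).
#' @return A data.frame with columns `substrate_id`, `product_id`,
#'   `pathway_ids` (list column of character vectors), `unspecified_residue`
#'   (logical).
#' @export
read_reactant_pairs <- function(path, format = c("tsv", "sif"),
                                sif_pathways = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv_plain(path)
    need <- c("substrate_id", "product_id")
    if (!all(need %in% names(df)))
      stop("reactant-pair file needs substrate_id and product_id columns",
           call. = FALSE)
    pw <- if ("pathway_ids" %in% names(df)) df$pathway_ids else rep("", nrow(df))
    pw[is.na(pw)] <- ""
    res <- if ("unspecified_residue" %in% names(df))
      as.logical(as.integer(df$unspecified_residue)) else rep(FALSE, nrow(df))
  } else {
    raw <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 3L) stop("SIF file needs three columns", call. = FALSE)
    df <- data.frame(substrate_id = as.character(raw[[1]]),
                     product_id = as.character(raw[[3]]),
                     stringsAsFactors = FALSE)
    pw <- rep("", nrow(df))
    res <- rep(FALSE, nrow(df))
    if (!is.null(sif_pathways)) {
      key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
      m <- match(key(df$substrate_id, df$product_id),
                 key(as.character(sif_pathways$substrate_id),
                     as.character(sif_pathways$product_id)))
      hit <- !is.na(m)
      if ("pathway_ids" %in% names(sif_pathways))
        pw[hit] <- as.character(sif_pathways$pathway_ids)[m[hit]]
      if ("unspecified_residue" %in% names(sif_pathways))
        res[hit] <- as.logical(as.integer(sif_pathways$unspecified_residue))[m[hit]]
    }
  }
  data.frame(substrate_id = as.character(df$substrate_id),
             product_id = as.character(df$product_id),
             pathway_ids = I(strsplit(pw, ";", fixed = TRUE)),
             unspecified_residue = res,
             stringsAsFactors = FALSE)
}

#' Flag metabolite ids carrying unspecified residues
#'
#' Compounds whose formula contains a generic residue (an "R" group) are not
#' fully specified molecules; pairs containing them are dropped during network
#' reconstruction. This helper marks ids from a formula lookup.
#'
#' @param ids Character vector of metabolite ids.
#' @param formulas Named character vector of formulas, names = ids.
#' @param pattern Regular expression identifying a residue in a formula.
#' @return Logical vector parallel to `ids`.
#' @export
flag_unspecified_residue <- function(ids, formulas, pattern = "R") {
  f <- formulas[ids]
  unname(!is.na(f) & grepl(pattern, f))
}

#' Reconstruct an organism-specific metabolic network
#'
#' Applies the two screening criteria to the reactant pairs: (1) pairs whose
#' pathway set does not intersect the organism's pathways are deleted;
#' (2) pairs involving a metabolite with an unspecified residue are deleted.
#' Surviving pairs become undirected edges of a simple graph (parallel pairs
#' collapse, self-pairs yield no edge); each node is a metabolite and each
#' edge a substrate-product relation.
#'
#' @param pairs Data frame as returned by [read_reactant_pairs()].
#' @param organism_pathways Character vector of the organism's pathway keys.
#' @return An [igraph::igraph] undirected simple graph with vertex name
#'   attributes set to metabolite ids.
#' @export
reconstruct_network <- function(pairs, organism_pathways) {
  if (length(organism_pathways) == 0L)
    stop("`organism_pathways` must be non-empty", call. = FALSE)
  keep <- vapply(pairs$pathway_ids,
                 function(p) any(p %in% organism_pathways), logical(1)) &
    !pairs$unspecified_residue
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- pairs[pairs$substrate_id != pairs$product_id, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    warning("no reactant pairs survive screening; returning an empty network",
            call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    pairs[, c("substrate_id", "product_id")], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

check_node <- function(net, node) {
  if (!node %in% igraph::V(net)$name)
    stop(sprintf("node '%s' is not in the network", node), call. = FALSE)
}

#' Node degree
#'
#' Number of distinct neighbours of a metabolite in the (simple, undirected)
#' metabolic network.
#'
#' @param net An igraph network from [reconstruct_network()].
#' @param node Metabolite id.
#' @return Non-negative integer count.
#' @export
node_degree <- function(net, node) {
  check_node(net, node)
  as.integer(igraph::degree(net, v = node))
}

#' Node clustering coefficient
#'
#' For a node with \eqn{n} neighbours, the ratio of realized to possible edges
#' among the neighbours: \eqn{2 e / (n (n - 1))} where \eqn{e} is the number
#' of edges between the \eqn{n} neighbours. Nodes of degree 0 or 1 are
#' assigned 0, matching the NetworkAnalyzer convention (the denominator is
#' undefined there).
#'
#' @inheritParams node_degree
#' @return Real in \[0, 1\].
#' @export
clustering_coefficient <- function(net, node) {
  check_node(net, node)
  cc <- unname(igraph::transitivity(net, type = "local", vids = node,
                                    isolates = "zero"))
  if (is.nan(cc) || is.na(cc)) cc <- 0
  cc
}

#' Topology descriptors for a set of metabolites
#'
#' Degree and clustering coefficient per metabolite. Metabolites absent from
#' the network receive degree 0 and clustering coefficient 0, with a warning
#' listing them.
#'
#' @param net An igraph network.
#' @param ids Character vector of metabolite ids.
#' @return data.frame with columns `metabolite_id`, `degree`,
#'   `clustering_coefficient`.
#' @export
topology_descriptors <- function(net, ids) {
  ids <- as.character(ids)
  present <- ids %in% igraph::V(net)$name
  if (any(!present))
    warning(sprintf("%d metabolite(s) absent from the network get zero topology: %s",
                    sum(!present),
                    paste(utils::head(unique(ids[!present]), 5L), collapse = ", ")),
            call. = FALSE)
  deg <- rep(0L, length(ids))
  cc <- rep(0, length(ids))
  if (any(present)) {
    deg[present] <- as.integer(igraph::degree(net, v = ids[present]))
    loc <- igraph::transitivity(net, type = "local", vids = ids[present],
                                isolates = "zero")
    loc[is.na(loc) | is.nan(loc)] <- 0
    cc[present] <- unname(loc)
  }
  data.frame(metabolite_id = ids, degree = deg, clustering_coefficient = cc,
             stringsAsFactors = FALSE)
}

#' Export a network as an edge list
#'
#' @param net An igraph network.
#' @param path Output path.
#' @param format `"tsv"` (substrate_id, product_id header) or `"sif"`
#'   (node, relation `rp`, node; isolated nodes written as single-column rows).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  el <- igraph::as_edgelist(net, names = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines("substrate_id\tproduct_id", con)
    if (nrow(el)) writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  } else {
    if (nrow(el)) writeLines(paste(el[, 1], "rp", el[, 2], sep = "\t"), con)
    iso <- setdiff(igraph::V(net)$name, c(el[, 1], el[, 2]))
    if (length(iso)) writeLines(iso, con)
  }
  invisible(path)
}

#' Concentration-tertile vs clustering-coefficient report
#'
#' Orders one organism's metabolites by concentration and cuts them into three
#' near-equal groups (Low/Medium/High); reports each group's mean
#' concentration and mean clustering coefficient. In metabolic networks a
#' denser reaction neighbourhood (higher clustering coefficient) tends to go
#' with higher concentration, which this table makes visible.
#'
#' @param dataset A `metaconc_dataset`.
#' @param net The organism's network.
#' @param organism Organism label to report on (default: the single organism
#'   present).
#' @return data.frame with one row per group: `group`, `n`,
#'   `mean_concentration`, `mean_neg_log_c`, `mean_clustering_coefficient`.
#' @export
tertile_cluster_report <- function(dataset, net, organism = NULL) {
  if (is.null(organism)) {
    orgs <- unique(dataset$organism)
    if (length(orgs) != 1L)
      stop("several organisms present; pass `organism`", call. = FALSE)
    organism <- orgs
  }
  d <- dataset[dataset$organism == organism, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("need at least 3 metabolites for a tertile report", call. = FALSE)
  conc <- d$concentration_molar
  if (anyNA(conc)) conc <- 10^(-d$neg_log_c)
  topo <- topology_descriptors(net, d$metabolite_id)
  ord <- order(conc)                     # stable: ties keep input order
  n <- nrow(d)
  base <- n %/% 3L
  sizes <- c(base, base, base) + c(n %% 3L >= 2L, n %% 3L >= 1L, 0L)
  grp <- rep(c("Low", "Medium", "High"), times = sizes)
  out <- data.frame(group = factor(grp, levels = c("Low", "Medium", "High")),
                    conc = conc[ord], nlc = -log10(conc[ord]),
                    cc = topo$clustering_coefficient[ord])
  agg <- do.call(rbind, lapply(split(out, out$group), function(x)
    data.frame(group = as.character(x$group[1]), n = nrow(x),
               mean_concentration = mean(x$conc),
               mean_neg_log_c = mean(x$nlc),
               mean_clustering_coefficient = mean(x$cc),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg
}
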