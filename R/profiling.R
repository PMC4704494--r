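#' Build compound interaction profiles
#'
#' Flattens pooled (replicate-mean) interaction coefficients into one vector
#' per compound, under one of three views: \code{combined} (all features x
#' all lines), \code{genotypes_only} (cell-number feature across all lines)
#' or \code{phenotypes_only} (all features in one reference line).
#'
#' @param x an \code{interaction_result}, or a 3-D array compound x line x
#'   feature of pooled coefficients.
#' @param subset profile view.
#' @param ref_line reference line (name or index) for
#'   \code{phenotypes_only}.
#' @param cellnum_feature cell-number feature (name or index) for
#'   \code{genotypes_only}.
#' @param exclude_controls drop control pseudo-compounds (only when \code{x}
#'   is an \code{interaction_result}).
#' @return numeric matrix compounds x profile cells with attribute
#'   \code{subset}.
#' @export
compound_profiles <- function(x, subset = c("combined", "genotypes_only",
                                            "phenotypes_only"),
                              ref_line = 1, cellnum_feature = "cell_number",
                              exclude_controls = TRUE) {
  subset <- match.arg(subset)
  if (inherits(x, "interaction_result")) {
    arr <- apply(x$pi, c(1, 2, 3), mean)   # pool replicates
    if (exclude_controls)
      arr <- arr[x$roles[dimnames(arr)[[1]]] %in% c(NA, "sample"), , ,
                 drop = FALSE]
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3)
    arr <- x
  }
  sel <- switch(subset,
    combined = arr,
    genotypes_only = arr[, , cellnum_feature, drop = FALSE],
    phenotypes_only = arr[, ref_line, , drop = FALSE])
  P <- matrix(sel, nrow = dim(arr)[1])
  rownames(P) <- dimnames(arr)[[1]]
  structure(P, subset = subset)
}

#' Pairwise Pearson correlation of compound profiles
#'
#' @param profiles matrix compounds x cells (rows are profiles).
#' @return symmetric correlation matrix with unit diagonal; pairs involving a
#'   constant profile are NA and the affected compounds are recorded in the
#'   \code{constant_profiles} attribute.
#' @export
profile_correlations <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  sds <- apply(profiles, 1, stats::sd, na.rm = TRUE)
  const <- rownames(profiles)[sds == 0]
  if (length(const))
    warning(sprintf("%d constant profile(s): correlations undefined",
                    length(const)))
  C <- suppressWarnings(
    stats::cor(t(profiles), use = "pairwise.complete.obs"))
  diag(C) <- 1
  C[sds == 0, ] <- NA; C[, sds == 0] <- NA
  diag(C)[sds == 0] <- NA
  structure(C, constant_profiles = const)
}

#' Profile distance matrix (1 - correlation)
#' @param correlations correlation matrix from
#'   \code{\link{profile_correlations}}.
#' @return distance matrix.
#' @export
profile_distances <- function(correlations) 1 - correlations

#' Complete-linkage hierarchical clustering of profile distances
#'
#' @param distance symmetric distance matrix (1 - correlation).
#' @return an \code{hclust} object (merge heights nondecreasing).
#' @export
cluster_profiles <- function(distance) {
  stopifnot(is.matrix(distance))
  if (!isSymmetric(unname(distance), tol = 1e-8))
    stop("distance matrix must be symmetric")
  stats::hclust(stats::as.dist(distance), method = "complete")
}

#' Extract size-bounded clusters below a height cut
#'
#' Cuts the dendrogram at \code{height_cut} and reports only clusters whose
#' size lies strictly between the bounds (defaults: more than 2 and fewer
#' than 10 members, i.e. 3..9).
#'
#' @param hc an \code{hclust} object.
#' @param height_cut tree cut height (default 0.6 on the 1 - correlation
#'   scale).
#' @param min_size,max_size inclusive size bounds of reported clusters.
#' @return named list of member character vectors.
#' @export
extract_clusters <- function(hc, height_cut = 0.6, min_size = 3,
                             max_size = 9) {
  grp <- stats::cutree(hc, h = height_cut)
  sizes <- table(grp)
  keep <- names(sizes)[sizes >= min_size & sizes <= max_size]
  out <- lapply(keep, function(g) names(grp)[grp == as.integer(g)])
  names(out) <- paste0("cluster_", seq_along(out))
  out
}

#' Export a dendrogram as Newick
#' @param hc an \code{hclust} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Build the filtered chemical-genetic interaction network
#'
#' Bipartite genotype-compound graph from significance calls: controls are
#' removed; compounds must interact with at most \code{max_genotypes}
#' genetic backgrounds and affect at least \code{min_features} distinct
#' phenotypic features; an edge links a compound to a genotype when at least
#' one feature (hence at least one phenotypic category) is significant for
#' that pair; genotypes without surviving edges are omitted.
#'
#' @param calls calls data.frame from \code{\link{test_interactions}}
#'   (columns compound, line, feature, role, p_adj, significant).
#' @param category_map named vector feature -> category.
#' @param max_genotypes breadth filter (default 3).
#' @param min_features minimum distinct significant features per compound
#'   (default 2, i.e. more than one).
#' @param exclude_controls drop rows whose role is not \code{sample}.
#' @return an \code{igraph} bipartite graph; vertices carry \code{type}
#'   ("compound"/"genotype"), edges carry \code{categories} (comma separated)
#'   and \code{min_p_adj}.
#' @export
build_network <- function(calls, category_map = NULL, max_genotypes = 3,
                          min_features = 2, exclude_controls = TRUE) {
  sig <- calls[calls$significant %in% TRUE, , drop = FALSE]
  if (exclude_controls && "role" %in% names(sig))
    sig <- sig[is.na(sig$role) | sig$role == "sample", , drop = FALSE]
  if (is.null(category_map))
    category_map <- default_category_map(unique(calls$feature))
  breadth <- tapply(sig$line, sig$compound, function(x) length(unique(x)))
  nfeat <- tapply(sig$feature, sig$compound, function(x) length(unique(x)))
  keep <- names(breadth)[breadth <= max_genotypes &
                           nfeat[names(breadth)] >= min_features]
  sig <- sig[sig$compound %in% keep, , drop = FALSE]
  if (nrow(sig) == 0)
    return(igraph::make_empty_graph(directed = FALSE))
  sig$category <- unname(category_map[sig$feature])
  edges <- stats::aggregate(
    cbind(p_adj) ~ compound + line, data = sig, FUN = min)
  cats <- stats::aggregate(category ~ compound + line, data = sig,
                           FUN = function(x) paste(sort(unique(x)),
                                                   collapse = ","))
  edges <- merge(edges, cats, by = c("compound", "line"))
  g <- igraph::graph_from_data_frame(
    edges[, c("compound", "line")], directed = FALSE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% edges$compound,
                              "compound", "genotype")
  igraph::E(g)$min_p_adj <- edges$p_adj
  igraph::E(g)$categories <- edges$category
  g
}

#' Export a network as GraphML plus a flat edge-list TSV
#' @param g igraph graph from \code{\link{build_network}}.
#' @param graphml_path,edgelist_path output files (NULL to skip either).
#' @return invisibly, the edge-list data.frame.
#' @export
export_network <- function(g, graphml_path = NULL, edgelist_path = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edgelist_path))
    utils::write.table(el, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(el)
}

#' Classify compound pairs by shared target selectivity or structure
#'
#' Target scheme: a pair is \code{shared_selectivity} iff the compounds'
#' annotated target sets intersect. Structure scheme: \code{similar_structure}
#' iff the pairwise chemical distance is strictly below the cutoff
#' (default 0.6, Tanimoto-distance convention).
#'
#' @param compounds compounds to pair (default: all annotated).
#' @param targets annotation data.frame (compound_id, target), possibly
#'   several rows per compound. Exactly one of \code{targets}/
#'   \code{distances} must be given.
#' @param distances symmetric pairwise distance matrix.
#' @param structure_cutoff strict upper bound for structural similarity.
#' @return data.frame (a, b, class) with attributes \code{scheme} and
#'   \code{n_excluded} (pairs dropped for missing annotation).
#' @export
classify_pairs <- function(compounds = NULL, targets = NULL, distances = NULL,
                           structure_cutoff = 0.6) {
  if (is.null(targets) == is.null(distances))
    stop("give exactly one of targets or distances")
  if (!is.null(targets)) {
    known <- unique(targets$compound_id)
    if (is.null(compounds)) compounds <- known
    missing <- setdiff(compounds, known)
    use <- setdiff(compounds, missing)
    tset <- split(targets$target, targets$compound_id)
    pairs <- utils::combn(sort(use), 2)
    cls <- apply(pairs, 2, function(p)
      if (length(intersect(tset[[p[1]]], tset[[p[2]]])) > 0)
        "shared_selectivity" else "no_shared_selectivity")
    scheme <- "target"
    n_excl <- choose(length(compounds), 2) - ncol(pairs)
  } else {
    known <- rownames(distances)
    if (is.null(compounds)) compounds <- known
    missing <- setdiff(compounds, known)
    use <- setdiff(compounds, missing)
    pairs <- utils::combn(sort(use), 2)
    cls <- apply(pairs, 2, function(p)
      if (distances[p[1], p[2]] < structure_cutoff)
        "similar_structure" else "different_structure")
    scheme <- "structure"
    n_excl <- choose(length(compounds), 2) - ncol(pairs)
  }
  structure(data.frame(a = pairs[1, ], b = pairs[2, ], class = cls,
                       stringsAsFactors = FALSE),
            scheme = scheme, n_excluded = n_excl)
}

#' Exact area under an ECDF over [-1, 1]
#'
#' Step-function integral of the right-continuous empirical cumulative
#' distribution of \code{x} over the fixed interval [-1, 1].
#' @param x sample values in [-1, 1].
#' @return the integral (a number in [0, 2]).
#' @export
ecdf_auc <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) stop("empty sample")
  knots <- c(-1, pmin(pmax(x, -1), 1), 1)
  heights <- c(seq(0, n) / n)          # F value on each inter-knot interval
  sum(diff(knots) * heights)
}

#' Resolution index (difference of ECDF areas between pair classes)
#'
#' The ECDF of profile correlations is computed separately for the two pair
#' classes; the index is AUC(second class) - AUC(first class), i.e. positive
#' when the first class (shared selectivity / similar structure) is the more
#' correlated one, since a right-shifted ECDF has a smaller area.
#'
#' @param correlations correlation matrix (or named square matrix subset) of
#'   compound profiles.
#' @param classes pair classification from \code{\link{classify_pairs}}.
#' @return list with \code{delta_auc}, per-class \code{auc}, per-class pair
#'   counts, and \code{n_dropped} (pairs with undefined correlation).
#' @export
resolution_index <- function(correlations, classes) {
  lv <- sort(unique(classes$class))
  pos <- intersect(c("shared_selectivity", "similar_structure"), lv)
  neg <- setdiff(lv, pos)
  if (length(pos) != 1 || length(neg) != 1)
    stop("need exactly two pair classes, one of them shared/similar")
  r <- correlations[cbind(classes$a, classes$b)]
  ok <- !is.na(r)
  n_dropped <- sum(!ok)
  r <- r[ok]; cl <- classes$class[ok]
  if (!any(cl == pos) || !any(cl == neg))
    stop("empty pair class")
  auc <- c(stats::setNames(ecdf_auc(r[cl == pos]), pos),
           stats::setNames(ecdf_auc(r[cl == neg]), neg))
  list(delta_auc = unname(auc[neg] - auc[pos]), auc = auc,
       n_pairs = stats::setNames(c(sum(cl == pos), sum(cl == neg)),
                                 c(pos, neg)),
       n_dropped = n_dropped)
}
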