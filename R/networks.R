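## Group-level co-occurrence networks and their comparison. The default
## construction correlates CLR-transformed abundances within each group
## (the Aitchison correction for compositional data); the alternative
## "consensus" construction scores each edge by the group's mean absolute
## sPCC perturbation added to the absolute reference correlation.

clr_transform <- function(x) {
  lx <- log(x + 1e-12)
  sweep(lx, 2L, colMeans(lx))
}

#' Build a per-group co-occurrence network
#'
#' @param x closed taxon-by-sample abundance matrix.
#' @param design a [sample_design()].
#' @param group group label to build the network for.
#' @param threshold minimum edge score for an edge to be kept
#'   (default 0.5).
#' @param method `"pearson"` (default): edge score = |Pearson correlation|
#'   over the group's own samples; `"consensus"`: mean |sPCC| over the
#'   group's samples plus |reference PCC| (reference group: |reference
#'   PCC| alone). `"consensus"` requires `ref`.
#' @param scale data scale for `method = "pearson"`: `"clr"` (default),
#'   `"log"` or `"abundance"`.
#' @param ref an [fit_reference()] model (required for
#'   `method = "consensus"`).
#' @return object of class `"iena_network"`: list with `group`, `nodes`,
#'   `edges` (data.frame `taxon_i`, `taxon_j`, `weight`), `threshold`,
#'   `method`.
#' @export
build_group_network <- function(x, design, group, threshold = 0.5,
                                method = c("pearson", "consensus"),
                                scale = c("clr", "log", "abundance"),
                                ref = NULL) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  x <- abundance_table(x)
  samples <- intersect(colnames(x), design_samples(design, group))
  if (length(samples) == 0L)
    stop("no samples in group '", group, "'", call. = FALSE)
  ref_group <- design_reference(design)
  if (method == "pearson") {
    xs <- x[, samples, drop = FALSE]
    xs <- switch(scale, clr = clr_transform(xs), log = log(xs + 1e-12),
                 abundance = xs)
    W <- abs(suppressWarnings(cor(t(xs))))
    W[is.na(W)] <- 0
    nodes <- rownames(x)
  } else {
    if (is.null(ref))
      stop("method = 'consensus' needs the reference model", call. = FALSE)
    nodes <- rownames(ref$cor)
    if (group == ref_group) {
      W <- abs(ref$cor)
    } else {
      sp <- lapply(samples, function(s)
        abs(spcc_matrix(ref, x[nodes, s], sample_id = s)))
      W <- Reduce(`+`, sp) / length(sp) + abs(ref$cor)
    }
  }
  diag(W) <- 0
  ut <- which(upper.tri(W) & W >= threshold, arr.ind = TRUE)
  edges <- data.frame(taxon_i = rownames(W)[ut[, 1]],
                      taxon_j = colnames(W)[ut[, 2]],
                      weight = W[ut], stringsAsFactors = FALSE)
  swap <- edges$taxon_i > edges$taxon_j
  tmp <- edges$taxon_i[swap]
  edges$taxon_i[swap] <- edges$taxon_j[swap]
  edges$taxon_j[swap] <- tmp
  edges <- edges[order(-edges$weight, edges$taxon_i, edges$taxon_j), ]
  rownames(edges) <- NULL
  structure(list(group = group, nodes = nodes, edges = edges,
                 threshold = threshold, method = method, scale = scale),
            class = "iena_network")
}

#' @export
print.iena_network <- function(x, ...) {
  cat("group network '", x$group, "': ", length(x$nodes), " taxa, ",
      nrow(x$edges), " edges (|score| >= ", x$threshold, ", ", x$method,
      ")\n", sep = "")
  invisible(x)
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character())
  paste(net$edges$taxon_i, net$edges$taxon_j, sep = "~")
}

#' Differential comparison of two group networks
#'
#' Partitions the edges of two networks (over the union of their node
#' sets) into A-only, B-only and shared, and scores each taxon by the
#' number of rewired (A-only + B-only) edges incident to it.
#'
#' @param net_a,net_b [build_group_network()] objects.
#' @return list: `a_only`, `b_only`, `shared` (edge data.frames) and
#'   `rewiring` (named per-taxon rewired-edge count over the node union).
#' @export
differential_network <- function(net_a, net_b) {
  nodes <- union(net_a$nodes, net_b$nodes)
  ka <- edge_keys(net_a); kb <- edge_keys(net_b)
  pick <- function(net, keys) {
    e <- net$edges[match(keys, edge_keys(net)), c("taxon_i", "taxon_j"),
                   drop = FALSE]
    rownames(e) <- NULL
    e
  }
  a_only <- pick(net_a, setdiff(ka, kb))
  b_only <- pick(net_b, setdiff(kb, ka))
  shared <- pick(net_a, intersect(ka, kb))
  rew <- stats::setNames(numeric(length(nodes)), nodes)
  for (e in list(a_only, b_only)) {
    if (nrow(e)) {
      tab <- table(c(e$taxon_i, e$taxon_j))
      rew[names(tab)] <- rew[names(tab)] + as.numeric(tab)
    }
  }
  list(a_only = a_only, b_only = b_only, shared = shared, rewiring = rew)
}

degrees <- function(net) {
  deg <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  wdeg <- deg
  if (nrow(net$edges)) {
    tab <- table(c(net$edges$taxon_i, net$edges$taxon_j))
    deg[names(tab)] <- as.numeric(tab)
    for (col in c("taxon_i", "taxon_j")) {
      ws <- tapply(net$edges$weight, net$edges[[col]], sum)
      wdeg[names(ws)] <- wdeg[names(ws)] + ws
    }
  }
  list(degree = deg, weighted = wdeg)
}

#' Rank network hubs
#'
#' Taxa ranked by degree, with weighted degree and then the taxon id as
#' tie-breaks; the top `k` are flagged as hubs. Betweenness centrality is
#' available as an alternative hubness score.
#'
#' @param net an [build_group_network()] object.
#' @param k number of hubs to flag (default 3).
#' @param hubness `"degree"` (default) or `"betweenness"`.
#' @return data.frame of class `"iena_hubs"`: `taxon`, `degree`,
#'   `weighted_degree`, `rank`, `hub`; attribute `group`.
#' @export
rank_hubs <- function(net, k = 3L, hubness = c("degree", "betweenness")) {
  hubness <- match.arg(hubness)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  d <- degrees(net)
  if (nrow(net$edges) == 0L)
    message("network '", net$group, "' has no edges; all degrees zero")
  if (hubness == "betweenness") {
    g <- igraph::graph_from_data_frame(net$edges[, c("taxon_i", "taxon_j")],
                                       directed = FALSE,
                                       vertices = net$nodes)
    btw <- igraph::betweenness(g, weights = NA)
    primary <- btw[net$nodes]
  } else {
    primary <- d$degree
  }
  ord <- order(-primary, -d$weighted, net$nodes)
  out <- data.frame(taxon = net$nodes[ord],
                    degree = d$degree[ord],
                    weighted_degree = d$weighted[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  out$hub <- out$rank <= k
  rownames(out) <- NULL
  class(out) <- c("iena_hubs", "data.frame")
  attr(out, "group") <- net$group
  attr(out, "hubness") <- hubness
  out
}

#' Disease-specific hubs across group networks
#'
#' A taxon is specific to a group when it is among that group's top-`k`
#' hubs and not among the top-`k` of any other group.
#'
#' @param hub_reports named list: group -> [rank_hubs()] result.
#' @param k hub cut-off (default 3).
#' @return named list: group -> character vector of group-specific hub
#'   taxa.
#' @export
disease_specific_hubs <- function(hub_reports, k = 3L) {
  if (length(hub_reports) < 2L)
    stop("need hub reports for >= 2 groups", call. = FALSE)
  tops <- lapply(hub_reports, function(h) h$taxon[h$rank <= k])
  out <- lapply(names(tops), function(g) {
    others <- unique(unlist(tops[setdiff(names(tops), g)]))
    setdiff(tops[[g]], others)
  })
  stats::setNames(out, names(tops))
}

#' Write a network as edge-list TSV or GraphML
#'
#' @param net an [build_group_network()] object.
#' @param path output file; format chosen by extension (`.tsv` or
#'   `.graphml`).
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
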