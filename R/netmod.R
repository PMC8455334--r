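## ---------------------------------------------------------------------------
## Interactome seed models, influence landscape, overlapping module
## detection, metanode cores, and group clustering coefficients.
##
## Module detection follows the influence-landscape idea of overlapping
## community analysis: every node radiates an attenuation zone; the summed
## landscape defines a centrality field whose hills are modules.  The
## concrete variant here (documented in the methods vignette) builds
## steepest-ascent basins on the field (restricted to triangle-supported
## edges so that single bridge edges cannot capture a community), merges
## basins whose inter-connectivity approaches their internal density, splits
## merged communities by spectral bisection where a sparse internal cut
## exists, and polishes labels by majority edge count.  Memberships are the
## normalized per-community zone masses, so every node carries a weight in
## every module and module member sets overlap.
## ---------------------------------------------------------------------------

#' Build a seed interactome model
#'
#' The node set is the seeds plus all their immediate interactome
#' neighbours; the edge set is the full induced subgraph on that node set
#' (neighbour-neighbour edges included).  Seeds absent from the interactome
#' are retained as isolated nodes and recorded in the `missing_seeds`
#' attribute rather than silently dropped.
#'
#' @param seeds character vector of seed gene ids (non-empty).
#' @param interactome an `interactome` object.
#' @return An `interactome` restricted to the seed neighbourhood, with
#'   attributes `seeds` and `missing_seeds`.
#' @export
build_seed_network <- function(seeds, interactome) {
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stopf("empty seed set")
  if (!length(interactome$nodes)) stopf("empty interactome")
  missing <- setdiff(seeds, interactome$nodes)
  present <- setdiff(seeds, missing)
  inc <- interactome$edges[, 1] %in% present | interactome$edges[, 2] %in% present
  nbrs <- unique(c(interactome$edges[inc, ]))
  nodes <- sort(unique(c(seeds, nbrs)))
  keep <- interactome$edges[, 1] %in% nodes & interactome$edges[, 2] %in% nodes
  net <- new_interactome(nodes, interactome$edges[keep, , drop = FALSE])
  attr(net, "seeds") <- seeds
  attr(net, "missing_seeds") <- missing
  net
}

#' Attenuated shortest-path influence landscape
#'
#' The influence of a node `v` is the attenuated reach
#' `sum over s with d(s, v) <= depth of lambda^d(s, v)` (the self term
#' contributes `lambda^0 = 1`), computed on unweighted shortest-path
#' distances.  Central, well-embedded nodes accumulate high influence.
#'
#' @param graph an `interactome`.
#' @param lambda attenuation per step, in (0, 1).
#' @param depth maximum path length contributing influence.
#' @return object of class `influence_landscape`: list with `influence`
#'   (named numeric), `lambda`, `depth`.
#' @export
influence_landscape <- function(graph, lambda = 0.5, depth = 3) {
  if (!length(graph$nodes)) stopf("empty graph")
  if (lambda <= 0 || lambda >= 1) stopf("`lambda` must lie in (0, 1)")
  assert_count(depth, "depth")
  g <- interactome_igraph(graph)
  ids <- sort(graph$nodes)
  D <- igraph::distances(g)[ids, ids, drop = FALSE]
  infl <- rowSums((lambda^D) * (D <= depth))
  structure(list(influence = infl, lambda = lambda, depth = depth),
            class = "influence_landscape")
}

## dense adjacency matrix in sorted node order
adjacency_dense <- function(graph, ids) {
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    A[graph$edges] <- 1
    A[graph$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Detect overlapping modules on an influence landscape
#'
#' See the module header and the methods vignette for the algorithm.  The
#' hard community labels are deterministic; ties in the ascent and in centre
#' identity are broken by influence, then degree, then lexicographic id.
#' Structurally indistinguishable tied centres (adjacent nodes with equal
#' influence and identical closed neighbourhoods, as in a complete graph)
#' collapse into a single centre class.
#'
#' @param landscape an [influence_landscape()] for `graph`.
#' @param graph an `interactome`.
#' @param tau membership floor: module member sets are the nodes whose
#'   normalized membership reaches `tau`.
#' @param merge_ratio communities are merged while the edge density between
#'   them is at least this fraction of the smaller internal density.
#' @return object of class `module_landscape`: `modules` (list of
#'   `centre`, `members`, `membership`, `centrality`), `assignment` (named
#'   hard labels by centre id), `membership_matrix` (nodes x centres,
#'   rows summing to 1), `influence`.
#' @export
detect_overlapping_modules <- function(landscape, graph, tau = 0.2,
                                       merge_ratio = 0.25) {
  stopifnot(inherits(landscape, "influence_landscape"))
  ids <- sort(graph$nodes)
  n <- length(ids)
  if (!n) stopf("empty graph")
  A <- adjacency_dense(graph, ids)
  lambda <- landscape$lambda
  infl_spec <- landscape$influence[ids]

  ## random-walk-with-restart zones; restart probability = lambda
  dg <- pmax(rowSums(A), 1)
  P <- A / dg
  Z <- lambda * solve(diag(n) - (1 - lambda) * P)
  dimnames(Z) <- list(ids, ids)
  infl <- colSums(Z)                     # detection field
  names(infl) <- ids
  eps <- 1e-9 * max(infl)
  deg <- setNames(rowSums(A), ids)
  adj <- lapply(ids, function(v) ids[A[v, ] > 0])
  names(adj) <- ids
  CN <- A %*% A                          # common-neighbour counts

  ## steepest ascent along triangle-supported edges
  target <- vapply(ids, function(v) {
    nb <- adj[[v]]
    if (!length(nb)) return(NA_character_)
    emb <- nb[CN[v, nb] > 0]
    cand <- if (length(emb)) emb else nb
    up <- cand[infl[cand] > infl[v] + eps]
    if (!length(up)) return(NA_character_)
    up[order(-infl[up], -deg[up], up)][1]
  }, character(1))
  root <- ids
  for (i in seq_len(n)) {
    nxt <- ifelse(is.na(target[root]), root, target[root])
    if (identical(nxt, root)) break
    root <- nxt
  }
  names(root) <- ids

  ## collapse tied adjacent twin centres (identical closed neighbourhoods)
  centres <- sort(unique(root))
  rep_of <- setNames(centres, centres)
  find_rep <- function(x) { while (rep_of[x] != x) x <- rep_of[x]; x }
  for (a in centres) for (b in centres) if (a < b) {
    ra <- find_rep(a); rb <- find_rep(b)
    if (ra != rb && abs(infl[ra] - infl[rb]) <= eps && rb %in% adj[[ra]] &&
        setequal(c(ra, adj[[ra]]), c(rb, adj[[rb]]))) {
      w <- if (deg[ra] != deg[rb]) { if (deg[ra] > deg[rb]) ra else rb } else min(ra, rb)
      rep_of[setdiff(c(ra, rb), w)] <- w
    }
  }
  root <- vapply(unname(root), find_rep, character(1))
  names(root) <- ids

  stronger <- function(ci, cj) {
    if (abs(infl[ci] - infl[cj]) > eps) { if (infl[ci] > infl[cj]) ci else cj }
    else if (deg[ci] != deg[cj]) { if (deg[ci] > deg[cj]) ci else cj }
    else min(ci, cj)
  }
  pair_ratio <- function(si, sj) {
    ni <- length(si); nj <- length(sj)
    eij <- sum(A[si, sj])
    di <- if (ni < 2) 1 else sum(A[si, si]) / 2 / choose(ni, 2)
    dj <- if (nj < 2) 1 else sum(A[sj, sj]) / 2 / choose(nj, 2)
    (eij / (ni * nj)) / max(min(di, dj), 1e-12)
  }
  merge_pass <- function(root) {
    repeat {
      cen <- sort(unique(root))
      if (length(cen) < 2) break
      mems <- split(ids, factor(root, levels = cen))
      best <- NULL; bestr <- -Inf
      for (i in seq_along(cen)) for (j in seq_along(cen)) if (i < j) {
        r <- pair_ratio(mems[[i]], mems[[j]])
        if (r > bestr) { bestr <- r; best <- c(i, j) }
      }
      if (bestr < merge_ratio) break
      ci <- cen[best[1]]; cj <- cen[best[2]]
      root[root == setdiff(c(ci, cj), stronger(ci, cj))] <- stronger(ci, cj)
    }
    root
  }
  ## spectral bisection split: accept a cut only if it is sparse relative to
  ## the parts' internal density (same criterion as the merge, inverted)
  split_unit <- function(mem) {
    if (length(mem) < 8) return(list(mem))
    Asub <- A[mem, mem]
    d <- rowSums(Asub)
    if (all(d == 0)) return(list(mem))
    Dm <- diag(1 / sqrt(pmax(d, 1)))
    L <- diag(length(mem)) - Dm %*% Asub %*% Dm
    ev <- eigen(L, symmetric = TRUE)
    f <- ev$vectors[, length(mem) - 1]
    p1 <- mem[f > 0]; p2 <- mem[f <= 0]
    if (length(p1) < 2 || length(p2) < 2) return(list(mem))
    if (pair_ratio(p1, p2) >= merge_ratio) return(list(mem))
    c(split_unit(p1), split_unit(p2))
  }

  root <- merge_pass(root)
  newroot <- root
  for (u in split(ids, root)) {
    parts <- split_unit(u)
    if (length(parts) > 1) for (p in parts)
      newroot[p] <- p[order(-infl[p], -deg[p], p)][1]
  }
  root <- merge_pass(newroot)

  ## polish: majority edge count, sticky on ties
  for (it in 1:3) {
    cen <- sort(unique(root))
    Bm <- matrix(0, n, length(cen), dimnames = list(ids, cen))
    Bm[cbind(ids, root)] <- 1
    M <- A %*% Bm
    nr <- cen[max.col(M + Bm * 1e-9, ties.method = "first")]
    names(nr) <- ids
    iso <- rowSums(M) == 0
    nr[iso] <- root[iso]
    if (identical(nr, root)) break
    root <- nr
  }

  cen <- sort(unique(root))
  Bm <- matrix(0, n, length(cen), dimnames = list(ids, cen))
  Bm[cbind(ids, root)] <- 1
  M <- sweep(t(Z) %*% Bm, 2, pmax(colSums(Bm), 1), "/")
  dimnames(M) <- list(ids, cen)
  s <- rowSums(M)
  norm <- M / ifelse(s > 0, s, 1)

  modules <- lapply(cen, function(c0) {
    w <- norm[, c0]
    members <- ids[w >= tau | root == c0]
    centrality <- sort_by_centrality(w[members] * infl_spec[members], members)
    list(centre = c0, members = members,
         membership = w[members][names(centrality)],
         centrality = centrality)
  })
  names(modules) <- cen
  structure(list(modules = modules, assignment = root,
                 membership_matrix = norm, influence = infl_spec,
                 tau = tau), class = "module_landscape")
}

## descending centrality with deterministic lexicographic tie-break
sort_by_centrality <- function(cent, ids) {
  ord <- order(-cent, ids)
  setNames(cent[ord], ids[ord])
}

#' @export
print.module_landscape <- function(x, ...) {
  cat(sprintf("module_landscape: %d modules over %d nodes\n",
              length(x$modules), length(x$assignment)))
  invisible(x)
}

#' Extract the metanode (central core) of a module
#'
#' The metanode is the `k` most central genes of a module, in descending
#' centrality (centrality = normalized membership x influence), with ties
#' broken by lexicographic gene id.  Modules smaller than `k` are returned
#' whole.
#'
#' @param module one element of a `module_landscape`'s `modules` list.
#' @param k metanode size (default 10).
#' @return character vector of gene ids, ordered by descending centrality.
#' @export
module_core <- function(module, k = 10) {
  assert_count(k, "k")
  if (!length(module$members)) stopf("empty module")
  head(names(module$centrality), k)
}

#' Functional core of a network: unique metanode genes
#'
#' @param metanodes list of metanode gene vectors (from [module_core()]).
#' @return deduplicated union of the metanode genes.
#' @export
network_core <- function(metanodes) {
  if (!length(metanodes)) stopf("need at least one metanode")
  unique(unlist(metanodes, use.names = FALSE))
}

#' Group clustering coefficient
#'
#' Mean and standard error of the local clustering coefficient (triangles
#' over possible triangles; nodes of degree < 2 contribute 0) of a gene
#' group, computed on the full graph.
#'
#' @param graph an `interactome`.
#' @param genes character vector of group members (subset of nodes).
#' @return list with `mean`, `sem`, `n`, and the per-gene `local` values.
#' @export
group_clustering_coefficient <- function(graph, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stopf("empty gene group")
  miss <- setdiff(genes, graph$nodes)
  if (length(miss))
    stopf("genes not in graph: %s", paste(head(miss, 5), collapse = ", "))
  g <- interactome_igraph(graph)
  cc <- igraph::transitivity(g, type = "localundirected", vids = genes)
  cc[!is.finite(cc)] <- 0
  names(cc) <- genes
  list(mean = mean(cc),
       sem = if (length(cc) > 1) sd(cc) / sqrt(length(cc)) else 0,
       n = length(cc), local = cc)
}

#' Adjusted Rand index between a detected assignment and a reference
#'
#' Thin wrapper over `mclust::adjustedRandIndex`, aligning on shared names.
#'
#' @param assignment named cluster labels (e.g. `module_landscape$assignment`).
#' @param reference named reference labels (e.g. planted membership).
#' @return the adjusted Rand index.
#' @export
module_recovery_ari <- function(assignment, reference) {
  common <- intersect(names(assignment), names(reference))
  if (!length(common)) stopf("no shared node names")
  mclust::adjustedRandIndex(assignment[common], reference[common])
}
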