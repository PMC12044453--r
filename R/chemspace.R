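# Chemical-space embeddings: kNN graph -> minimum spanning tree -> tree
# layout (tree-map style), and t-SNE.

#' k-nearest-neighbour graph over fingerprint distances
#'
#' Connects each molecule to its `k` nearest neighbours under Tanimoto
#' distance (1 - similarity). `k` is truncated to `n - 1` for small sets.
#' Exact search is used up to `exact_limit` molecules; above it a MinHash
#' locality-sensitive-hashing search is used, with `kc` controlling the
#' candidate-pool expansion (pool trimmed to `k * kc` candidates per query
#' before exact rescoring).
#'
#' @param fps a `fingerprint_set` (or SMILES vector with `kind`).
#' @param k neighbours per node (default 50).
#' @param kc query-expansion factor for the approximate mode (default 10).
#' @param mode `"auto"`, `"exact"` or `"lsh"`.
#' @param exact_limit library size above which `"auto"` switches to LSH.
#' @param kind fingerprint kind when `fps` is a SMILES vector.
#' @param seed seed for the LSH hash functions.
#' @return A `knn_graph` list: `edges` (data frame `i`, `j`, `weight`,
#'   undirected, deduplicated), `n`, `k`, `mode`.
#' @export
knn_graph <- function(fps, k = 50L, kc = 10L,
                      mode = c("auto", "exact", "lsh"),
                      exact_limit = 50000L, kind = "morgan2_1024",
                      seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(fps, "fingerprint_set")) fps <- fingerprint(fps, kind)
  n <- length(fps$bits)
  if (n < 2L) stop("need at least 2 fingerprints")
  k <- min(as.integer(k), n - 1L)
  if (mode == "auto") mode <- if (n <= exact_limit) "exact" else "lsh"

  if (mode == "exact") {
    nbrs <- exact_knn(fps, k)
  } else {
    nbrs <- lsh_knn(fps, k, kc, seed)
  }
  edges <- unique(data.frame(
    i = pmin(nbrs$i, nbrs$j), j = pmax(nbrs$i, nbrs$j),
    weight = nbrs$weight, stringsAsFactors = FALSE))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n, k = k, mode = mode),
            class = "knn_graph")
}

exact_knn <- function(fps, k) {
  n <- length(fps$bits)
  i <- rep.int(seq_len(n), lengths(fps$bits))
  j <- unlist(fps$bits, use.names = FALSE) + 1L
  x <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, fps$nbits))
  inter <- as.matrix(Matrix::tcrossprod(x))
  pop <- lengths(fps$bits)
  un <- outer(pop, pop, `+`) - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1))
  dist <- 1 - sim
  diag(dist) <- Inf
  rows <- lapply(seq_len(n), function(a) {
    ord <- order(dist[a, ], seq_len(n))[seq_len(k)]
    data.frame(i = a, j = ord, weight = dist[a, ord])
  })
  do.call(rbind, rows)
}

# MinHash signatures + banded buckets; candidates rescored exactly.
lsh_knn <- function(fps, k, kc, seed, n_hashes = 128L, band_rows = 2L) {
  n <- length(fps$bits)
  p <- 2147483629
  hp <- with_seed(seed, list(a = sample.int(p - 1L, n_hashes),
                             b = sample.int(p - 1L, n_hashes)))
  sig <- matrix(NA_real_, n_hashes, n)
  for (m in seq_len(n)) {
    bits <- fps$bits[[m]] + 1
    if (length(bits) == 0L) bits <- 0
    for (h in seq_len(n_hashes)) {
      sig[h, m] <- min((hp$a[h] * bits + hp$b[h]) %% p)
    }
  }
  n_bands <- n_hashes %/% band_rows
  cand <- vector("list", n)
  for (bnd in seq_len(n_bands)) {
    rows <- ((bnd - 1L) * band_rows + 1L):(bnd * band_rows)
    key <- apply(sig[rows, , drop = FALSE], 2L, paste, collapse = ",")
    buckets <- split(seq_len(n), key)
    for (bk in buckets) {
      if (length(bk) > 1L) {
        for (m in bk) cand[[m]] <- c(cand[[m]], bk)
      }
    }
  }
  pool_size <- max(k * kc, 50L)
  rows <- lapply(seq_len(n), function(a) {
    cs <- setdiff(unique(cand[[a]]), a)
    if (length(cs) < k) {
      # top up from signature agreement so every node has k neighbours
      agree <- colSums(sig == sig[, a])
      agree[a] <- -Inf
      extra <- order(agree, decreasing = TRUE)[seq_len(min(n - 1L,
                                                           pool_size))]
      cs <- unique(c(cs, extra))
    }
    if (length(cs) > pool_size) {
      agree <- colSums(sig[, cs, drop = FALSE] == sig[, a])
      cs <- cs[order(agree, decreasing = TRUE)[seq_len(pool_size)]]
    }
    d <- vapply(cs, function(b) {
      inter <- length(intersect(fps$bits[[a]], fps$bits[[b]]))
      un <- length(fps$bits[[a]]) + length(fps$bits[[b]]) - inter
      if (un == 0) 0 else 1 - inter / un
    }, 0)
    ord <- order(d, cs)[seq_len(min(k, length(cs)))]
    data.frame(i = a, j = cs[ord], weight = d[ord])
  })
  do.call(rbind, rows)
}

#' Minimum spanning tree of a weighted graph
#'
#' Kruskal's algorithm with union-find; one tree per connected component
#' (a spanning forest). Ties are broken deterministically by edge order.
#'
#' @param edges data frame with `i`, `j`, `weight` (1-based vertices).
#' @param n number of vertices.
#' @return Data frame of the forest's edges (`i`, `j`, `weight`).
#' @export
minimum_spanning_tree <- function(edges, n) {
  if (nrow(edges) == 0L) {
    return(edges)
  }
  ord <- order(edges$weight, edges$i, edges$j)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  keep <- logical(nrow(edges))
  for (e in ord) {
    ra <- find(edges$i[e])
    rb <- find(edges$j[e])
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
    }
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tree-map style layout of a kNN graph
#'
#' Reduces the graph to its minimum spanning forest and lays every tree
#' out deterministically: the tree is rooted at its topological centre
#' and children are placed on circles of increasing radius, each subtree
#' receiving an angular wedge proportional to its size. Components are
#' offset horizontally.
#'
#' @param graph a [knn_graph()] (or any list with `edges` and `n`).
#' @param seed unused; accepted for interface symmetry. The layout is
#'   deterministic.
#' @return An `embedding_result`: `coords` (data frame `id`, `x`, `y`),
#'   `edges` (the spanning forest), `method = "tmap"`, `params`.
#' @export
tmap_layout <- function(graph, seed = NULL) {
  n <- graph$n
  if (is.null(n) || n < 1L) stop("empty graph")
  mst <- minimum_spanning_tree(graph$edges, n)
  adj <- vector("list", n)
  if (nrow(mst)) {
    for (e in seq_len(nrow(mst))) {
      i <- mst$i[e]; j <- mst$j[e]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  coords <- matrix(0, n, 2)
  visited <- logical(n)
  xoff <- 0
  for (start in seq_len(n)) {
    if (visited[start]) next
    comp <- bfs_component(adj, start)
    visited[comp] <- TRUE
    root <- tree_center(adj, comp)
    pos <- radial_tree_layout(adj, root)
    pos[, 1] <- pos[, 1] + xoff
    coords[comp, ] <- pos[match(comp, as.integer(rownames(pos))), ]
    xoff <- max(coords[comp, 1]) + 2
  }
  structure(list(
    coords = data.frame(id = seq_len(n), x = coords[, 1], y = coords[, 2]),
    edges = mst, method = "tmap",
    params = list(k = graph$k, mode = graph$mode)),
    class = "embedding_result")
}

bfs_component <- function(adj, start) {
  seen <- integer(0)
  queue <- start
  mark <- logical(length(adj))
  mark[start] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    seen <- c(seen, v)
    for (w in adj[[v]]) {
      if (!mark[w]) {
        mark[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  sort(seen)
}

# topological centre: repeatedly peel leaves (deterministic)
tree_center <- function(adj, comp) {
  deg <- lengths(adj)[comp]
  alive <- setNames(rep(TRUE, length(comp)), comp)
  degc <- setNames(deg, comp)
  remaining <- comp
  while (length(remaining) > 2L) {
    leaves <- remaining[degc[as.character(remaining)] <= 1L]
    if (length(leaves) == 0L) break
    for (lf in leaves) {
      alive[as.character(lf)] <- FALSE
      for (w in adj[[lf]]) {
        if (isTRUE(alive[as.character(w)])) {
          degc[as.character(w)] <- degc[as.character(w)] - 1L
        }
      }
    }
    remaining <- remaining[alive[as.character(remaining)]]
  }
  min(remaining)
}

radial_tree_layout <- function(adj, root) {
  # subtree sizes by DFS from root
  order <- integer(0)
  parent <- integer(0)
  stack <- root
  par <- setNames(integer(1), root)
  par[as.character(root)] <- 0L
  seen <- c(root)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    kids <- sort(setdiff(adj[[v]], seen))
    for (kd in kids) {
      par[as.character(kd)] <- v
      seen <- c(seen, kd)
      stack <- c(stack, kd)
    }
  }
  size <- setNames(rep(1, length(order)), order)
  for (v in rev(order)) {
    p <- par[as.character(v)]
    if (p > 0L) {
      size[as.character(p)] <- size[as.character(p)] + size[as.character(v)]
    }
  }
  ang_lo <- setNames(rep(0, length(order)), order)
  ang_hi <- setNames(rep(2 * pi, length(order)), order)
  depth <- setNames(rep(0, length(order)), order)
  for (v in order) {
    kids <- sort(setdiff(adj[[v]], if (par[as.character(v)] > 0L)
      par[as.character(v)] else integer(0)))
    kids <- kids[as.character(kids) %in% names(par)]
    kids <- kids[par[as.character(kids)] == v]
    if (length(kids) == 0L) next
    lo <- ang_lo[as.character(v)]
    span <- ang_hi[as.character(v)] - lo
    tot <- sum(size[as.character(kids)])
    for (kd in kids) {
      frac <- size[as.character(kd)] / tot
      ang_lo[as.character(kd)] <- lo
      ang_hi[as.character(kd)] <- lo + span * frac
      depth[as.character(kd)] <- depth[as.character(v)] + 1
      lo <- lo + span * frac
    }
  }
  mid <- (ang_lo + ang_hi) / 2
  r <- depth
  pos <- cbind(r * cos(mid), r * sin(mid))
  rownames(pos) <- names(depth)
  pos[as.character(order), , drop = FALSE]
}

#' t-SNE embedding of fingerprints
#'
#' Two-dimensional t-distributed stochastic neighbour embedding of the
#' (dense) fingerprint matrix, with the perplexity and iteration defaults
#' used for fragment chemical-space maps (perplexity 40, 300 iterations).
#' If `n <= 3 * perplexity` the perplexity is reduced with a warning;
#' fewer than 5 molecules is an error. A fixed seed gives identical
#' coordinates on repeat runs.
#'
#' @param fps a `fingerprint_set` (or SMILES vector with `kind`).
#' @param perplexity nearest-neighbour bandwidth (default 40).
#' @param n_iter optimization iterations (default 300).
#' @param seed random seed.
#' @param kind fingerprint kind when `fps` is a SMILES vector.
#' @return An `embedding_result` with `coords`, `method = "tsne"` and the
#'   parameters actually used.
#' @export
tsne_embed <- function(fps, perplexity = 40, n_iter = 300L, seed = 42L,
                       kind = "morgan2_1024") {
  if (!inherits(fps, "fingerprint_set")) fps <- fingerprint(fps, kind)
  n <- length(fps$bits)
  if (n < 5L) stop("need at least 5 molecules for t-SNE")
  payload <- list(bits = fps$bits, nbits = fps$nbits,
                  perplexity = perplexity, n_iter = n_iter, seed = seed)
  res <- call_chemtools("tsne", payload = payload)
  if (isTRUE(res$reduced)) {
    warning(sprintf("perplexity reduced to %.0f for n = %d",
                    res$perplexity_used, n))
  }
  coords <- do.call(rbind, lapply(res$coords, unlist))
  structure(list(
    coords = data.frame(id = seq_len(n), x = coords[, 1], y = coords[, 2]),
    edges = NULL, method = "tsne",
    params = list(perplexity = res$perplexity_used, n_iter = n_iter,
                  seed = seed, fingerprint = fps$kind)),
    class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result: %s, %d points%s>\n", x$method,
              nrow(x$coords),
              if (!is.null(x$edges)) sprintf(", %d tree edges",
                                             nrow(x$edges)) else ""))
  invisible(x)
}
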