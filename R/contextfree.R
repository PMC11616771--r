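#' Sequence embedders
#'
#' An embedder is any function mapping an amino-acid string to a fixed-
#' length numeric vector, deterministically (the same sequence always
#' yields the same vector). Production pipelines plug in precomputed tables
#' from a protein language model via [read_embedding_table()]; the built-in
#' [hash_embedder()] is a fast, fully deterministic k-mer hashing embedder
#' suitable for synthetic benchmarks: overlapping k-mers are hashed to
#' signed positions of a d-dimensional vector and accumulated, so sequences
#' sharing subsequences land near each other.
#'
#' @param d embedding dimension (default 1024, matching the dimensionality
#'   of common protein language-model embeddings).
#' @param k k-mer length.
#' @return a function `f(sequence) -> numeric(d)`.
#' @export
hash_embedder <- function(d = 1024, k = 3) {
  force(d); force(k)
  function(sequence) {
    sequence <- toupper(as.character(sequence))
    n <- nchar(sequence)
    if (is.na(sequence) || n == 0) stop("empty sequence")
    v <- numeric(d)
    if (n < k) {
      kmers <- sequence
    } else {
      kmers <- substring(sequence, 1:(n - k + 1), k:n)
    }
    codes <- vapply(kmers, str_hash, numeric(1), USE.NAMES = FALSE)
    idx <- (codes %% d) + 1
    sgn <- ifelse((codes %/% d) %% 2 == 0, 1, -1)
    for (i in seq_along(idx)) v[idx[i]] <- v[idx[i]] + sgn[i]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    v
  }
}

# deterministic polynomial rolling hash (31-adic, mod 2^26), platform-stable
str_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 67108864
  h
}

#' Embed protein sequences gene-by-gene
#'
#' Applies an embedder to each gene's sequence. A gene whose embedding
#' fails is omitted (with a message) rather than aborting the table.
#'
#' @param sequences named character vector (gene -> amino-acid string).
#' @param embedder a function as returned by [hash_embedder()], or any
#'   deterministic `f(sequence) -> numeric vector`.
#' @return gene x d numeric matrix (an embedding table).
#' @export
embed_sequences <- function(sequences, embedder = hash_embedder()) {
  if (length(sequences) == 0) {
    return(matrix(numeric(), 0, 0))
  }
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("sequences must be named by gene symbol")
  }
  rows <- lapply(names(sequences), function(g) {
    tryCatch(embedder(sequences[[g]]), error = function(e) {
      message("embedding failed for ", g, ": ", conditionMessage(e))
      NULL
    })
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) stop("all embeddings failed")
  d <- length(rows[[which(ok)[1]]])
  if (any(vapply(rows[ok], length, integer(1)) != d)) {
    stop("embedder returned vectors of unequal dimension")
  }
  m <- do.call(rbind, rows[ok])
  rownames(m) <- names(sequences)[ok]
  colnames(m) <- sprintf("e%d", seq_len(d))
  m
}

#' Build the protein-protein interaction graph
#'
#' Keeps only edges with trusted evidence (by default manually curated or
#' experimentally validated interactions), drops self-loops, and collapses
#' duplicate/reciprocal records into a simple undirected graph.
#'
#' @param edges data frame with columns `gene1`, `gene2`, `evidence_class`.
#' @param accepted evidence classes to retain.
#' @return an undirected simple `igraph` graph.
#' @export
build_ppi_graph <- function(edges,
                            accepted = c("curated", "experimental")) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  keep <- edges$evidence_class %in% accepted & edges$gene1 != edges$gene2
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges[, c("gene1", "gene2")],
                                     directed = FALSE)
  igraph::simplify(g)
}

#' Embed PPI graph nodes by truncated random walks
#'
#' Node embeddings in the spirit of unbiased node2vec/DeepWalk: uniform
#' random walks are sampled from every node, token co-occurrences within a
#' sliding window are accumulated, and the positive pointwise mutual
#' information (PPMI) matrix of the co-occurrence counts is factorized by
#' truncated SVD into d-dimensional node vectors. With unit walk bias
#' (p = q = 1) this matches the canonical defaults of walk-based node
#' embedding: 10 walks per node of length 80, window 10, d = 64.
#' Fixed seed gives bit-identical output.
#'
#' @param graph an undirected `igraph` graph.
#' @param d embedding dimension.
#' @param n_walks walks started per node.
#' @param walk_length steps per walk.
#' @param window co-occurrence window (positions either side).
#' @param seed integer seed.
#' @return gene x d numeric matrix over the graph's nodes. Isolated nodes
#'   (degree 0) receive zero vectors.
#' @export
embed_ppi_nodes <- function(graph, d = 64, n_walks = 10, walk_length = 80,
                            window = 10, seed = 1L) {
  nv <- igraph::vcount(graph)
  if (nv == 0) stop("cannot embed an empty graph")
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(nv))
  adj <- igraph::as_adj_list(graph, mode = "all")
  deg <- lengths(adj)
  co <- matrix(0, nv, nv)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  # one chain per (start node, walk); all chains advance in lockstep using
  # a flat CSR adjacency, so each step is a single vectorized draw
  starts <- rep(which(deg > 0), each = n_walks)
  if (length(starts) > 0) {
    adj_flat <- as.integer(unlist(adj))
    adj_start <- c(0L, cumsum(deg))        # 0-based offsets
    steps <- matrix(0L, length(starts), walk_length)
    steps[, 1] <- starts
    cur <- starts
    for (s in seq_len(walk_length - 1L)) {
      pick <- floor(stats::runif(length(cur)) * deg[cur]) + 1L
      cur <- adj_flat[adj_start[cur] + pick]
      steps[, s + 1L] <- cur
    }
    # symmetric window co-occurrence, aggregated per offset
    for (off in seq_len(min(window, walk_length - 1L))) {
      i <- as.vector(steps[, seq_len(walk_length - off)])
      j <- as.vector(steps[, seq_len(walk_length - off) + off])
      cnt <- tabulate(i + (j - 1L) * nv, nbins = nv * nv)
      cmat <- matrix(cnt, nv, nv)
      co <- co + cmat + t(cmat)
    }
  }
  tot <- sum(co)
  emb <- matrix(0, nv, d)
  if (tot > 0) {
    rs <- rowSums(co); cs <- colSums(co)
    active <- which(rs > 0)
    pmi <- log((co[active, active, drop = FALSE] * tot) /
                 outer(rs[active], cs[active]))
    pmi[!is.finite(pmi) | pmi < 0] <- 0
    sv <- svd(pmi, nu = min(d, length(active)), nv = 0)
    keep <- seq_len(min(d, length(active)))
    vecs <- sv$u[, keep, drop = FALSE] %*% diag(sqrt(sv$d[keep]),
                                               nrow = length(keep))
    # fix the SVD sign ambiguity so output is reproducible
    for (j in seq_len(ncol(vecs))) {
      piv <- which.max(abs(vecs[, j]))
      if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
    }
    emb[active, seq_len(ncol(vecs))] <- vecs
  }
  rownames(emb) <- nodes
  colnames(emb) <- sprintf("e%d", seq_len(d))
  emb
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Absolute-difference pair features
#'
#' The feature vector of a gene pair from an embedding table is the
#' elementwise absolute difference of the two genes' vectors: entries are
#' non-negative and invariant to gene order. A pair with either gene absent
#' from the table gets an all-missing vector.
#'
#' @param pairs a `gene_pairs` object.
#' @param table gene x d embedding matrix.
#' @param source source tag for the resulting block.
#' @return a `feature_block` of dimension N x d.
#' @export
pair_absdiff_block <- function(pairs, table, source = "emb") {
  stopifnot(inherits(pairs, "gene_pairs"))
  d <- ncol(table)
  m <- matrix(NA_real_, nrow(pairs), d)
  ia <- match(pairs$gene_a, rownames(table))
  ib <- match(pairs$gene_b, rownames(table))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) {
    m[ok, ] <- abs(table[ia[ok], , drop = FALSE] -
                     table[ib[ok], , drop = FALSE])
  }
  if (any(!ok)) {
    message(sum(!ok), " pair(s) with a gene absent from the embedding table",
            " -> missing features")
  }
  colnames(m) <- sprintf("%s_d%d", source, seq_len(d))
  feature_block(pairs, m, source)
}

#' Absolute-difference features for a single pair
#'
#' @param pair one-row `gene_pairs`.
#' @param table gene x d embedding matrix.
#' @return numeric vector of length `ncol(table)`.
#' @export
pair_absdiff_features <- function(pair, table) {
  blk <- suppressMessages(pair_absdiff_block(pair[1, , drop = FALSE], table))
  blk$matrix[1, ]
}
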