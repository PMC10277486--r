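# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's production code paths.

# --- term hierarchy oracles -----------------------------------------------

# descendant set by exhaustive repeated edge expansion
oracle_descendants <- function(edges, t) {
  out <- t
  repeat {
    nxt <- unique(c(out, edges$child[edges$parent %in% out]))
    if (length(nxt) == length(out)) return(out)
    out <- nxt
  }
}

oracle_frequency <- function(edges, counts, t) {
  sum(counts[oracle_descendants(edges, t)])
}

oracle_ancestors <- function(edges, t) {
  out <- t
  repeat {
    nxt <- unique(c(out, edges$parent[edges$child %in% out]))
    if (length(nxt) == length(out)) return(out)
    out <- nxt
  }
}

# Lin similarity by enumerating every common ancestor
oracle_lin <- function(edges, counts, root, t1, t2) {
  if (t1 == t2) return(1)
  N <- oracle_frequency(edges, counts, root)
  p <- function(t) oracle_frequency(edges, counts, t) / N
  p1 <- p(t1); p2 <- p(t2)
  if (p1 >= 1 || p2 >= 1) return(0)
  common <- intersect(oracle_ancestors(edges, t1), oracle_ancestors(edges, t2))
  max(vapply(common, function(t) 2 * log(p(t)) / (log(p1) + log(p2)),
             numeric(1)))
}

# --- gene-set similarity oracles ------------------------------------------

oracle_jaccard <- function(sa, sb) {
  u <- length(union(sa, sb))
  if (u == 0) 0 else length(intersect(sa, sb)) / u
}

# double-loop metabolite similarity over explicit GO sets
oracle_sm <- function(G1, G2, go_sets) {
  sg <- function(g, G) max(vapply(G, function(h)
    oracle_jaccard(go_sets[[g]], go_sets[[h]]), numeric(1)))
  (sum(vapply(G1, sg, numeric(1), G = G2)) +
     sum(vapply(G2, sg, numeric(1), G = G1))) /
    (length(G1) + length(G2))
}

# --- Vicus oracle ----------------------------------------------------------

# per-node dense-inversion reconstruction weights, written independently
oracle_B <- function(W, K, alpha) {
  W <- unclass(W)
  n <- nrow(W)
  ids <- rownames(W)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- W[i, ]
    s[i] <- -Inf
    cand <- which(s > 0)
    Ksel <- K
    if (!length(cand)) {
      cand <- setdiff(seq_len(n), i)
      Ksel <- 1L
    }
    ord <- cand[order(-s[cand], ids[cand])]
    nbr <- ord[seq_len(min(Ksel, length(ord)))]
    ver <- c(nbr, i)
    Wi <- W[ver, ver, drop = FALSE]
    rs <- rowSums(Wi)
    diag(Wi)[rs == 0] <- 1
    Si <- Wi / rowSums(Wi)
    k1 <- length(ver)
    inv <- solve(diag(k1) - alpha * Si)
    beta <- (1 - alpha) * inv[k1, ]
    if (1 - beta[k1] < 1e-12) {
      B[i, nbr] <- 1 / length(nbr)
    } else {
      B[i, nbr] <- beta[seq_len(length(nbr))] / (1 - beta[k1])
    }
  }
  dimnames(B) <- dimnames(W)
  B
}

# --- metric oracles: exhaustive threshold enumeration ----------------------

oracle_metrics <- function(scores, labels) {
  y <- labels > 0
  P <- sum(y); N <- sum(!y)
  # AUC: all positive-negative pairs, ties get half credit
  pairs <- expand.grid(p = which(y), n = which(!y))
  cmp <- sign(scores[pairs$p] - scores[pairs$n])
  auc <- mean(ifelse(cmp > 0, 1, ifelse(cmp == 0, 0.5, 0)))
  # PR points at every distinct threshold, descending
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- f1 <- numeric(length(th))
  for (k in seq_along(th)) {
    sel <- scores >= th[k]
    tp <- sum(sel & y); fp <- sum(sel & !y)
    prec[k] <- tp / (tp + fp)
    rec[k] <- tp / P
    f1[k] <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + (P - tp))
  }
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auc = auc, aupr = aupr, f1 = max(f1))
}

# --- numerical differentiation --------------------------------------------

numeric_grad <- function(f, X, h = 1e-5) {
  G <- X
  for (k in seq_along(X)) {
    Xp <- X; Xp[k] <- X[k] + h
    Xm <- X; Xm[k] <- X[k] - h
    G[k] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# --- fixtures --------------------------------------------------------------

random_similarity <- function(n, seed, sparsity = 0, ids = NULL) {
  set.seed(seed)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  if (sparsity > 0) {
    mask <- matrix(runif(n * n) < sparsity, n, n)
    mask <- mask | t(mask)
    S[mask] <- 0
  }
  diag(S) <- 1
  similarity_network(S, node_ids = ids)
}

# similarity networks aligned with interaction_matrix default registries
random_met_similarity <- function(n, seed, ...)
  random_similarity(n, seed, ..., ids = paste0("m", seq_len(n)))
random_dis_similarity <- function(n, seed, ...)
  random_similarity(n, seed, ..., ids = paste0("d", seq_len(n)))

# diamond hierarchy: root with children a, b; both parents of c
diamond_edges <- data.frame(child  = c("a", "b", "c", "c"),
                            parent = c("root", "root", "a", "b"))
diamond_counts <- c(root = 1, a = 1, b = 1, c = 1)
diamond_dag <- function() term_dag(diamond_edges, diamond_counts)
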