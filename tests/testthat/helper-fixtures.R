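# Shared fixtures, all built in code.

# Bipartite pair on 2*nside + 2*nside vertices where the first half of X is
# completely joined to the first half of Y and nothing else: d(X, Y) = 1/4
# but d(X1, Y1) = 1, the canonical irregular construction.
makeHalfCompletePair <- function(nside) {
  n <- 2 * nside
  a <- matrix(0L, 2 * n, 2 * n)
  a[seq_len(nside), n + seq_len(nside)] <- 1L
  list(g = simpleGraph(a + t(a)), X = seq_len(n), Y = n + seq_len(n),
       X1 = seq_len(nside), Y1 = n + seq_len(nside))
}

makeCompleteGraph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  simpleGraph(a)
}

makeEmptyGraph <- function(n) simpleGraph(matrix(0L, n, n))

# Two disjoint cliques of the given size.
makeTwoCliques <- function(size = 5) {
  n <- 2 * size
  a <- matrix(0L, n, n)
  a[seq_len(size), seq_len(size)] <- 1L
  a[size + seq_len(size), size + seq_len(size)] <- 1L
  diag(a) <- 0L
  simpleGraph(a)
}

# Exhaustive-mapping clustering accuracy for small label sets: tries every
# injective mapping of predicted labels onto truth labels.
exhaustiveAccuracy <- function(truth, predicted) {
  tl <- sort(unique(truth)); pl <- sort(unique(predicted))
  s <- max(length(tl), length(pl))
  tl <- c(tl, rep(-seq_len(s - length(tl)), length.out = s - length(tl)))
  pl <- c(pl, rep(-1000 - seq_len(s - length(pl)),
                  length.out = s - length(pl)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (pp in perms(seq_len(s))) {
    mapped <- tl[pp][match(predicted, pl)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

# Direct recount of a certificate against the definitional inequality.
certificateIsValid <- function(g, X, Y, verdict) {
  A <- verdict@certA; B <- verdict@certB
  eps <- verdict@eps
  d <- pairDensity(g, X, Y)
  dAB <- pairDensity(g, A, B)
  all(A %in% X) && all(B %in% Y) &&
    length(A) > eps * length(X) && length(B) > eps * length(Y) &&
    abs(d - dAB) >= eps
}
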