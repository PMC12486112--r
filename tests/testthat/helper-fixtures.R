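# Shared in-code fixtures for the test suite.

# tiny dataset: n cells on a line with per-cell clone labels
makeToyDataset <- function(n = 30, nGenes = 5, seed = 11) {
  set.seed(seed)
  emb <- cbind(seq_len(n) + rnorm(n, sd = 0.01), rnorm(n, sd = 0.01))
  expr <- matrix(abs(rnorm(nGenes * n)), nGenes, n,
                 dimnames = list(paste0("g", seq_len(nGenes)),
                                 paste0("c", seq_len(n))))
  clone <- rep(c("A", "B", NA), length.out = n)
  CellDataset(expr, emb, cloneId = clone,
              clusterId = rep(c("x", "y"), length.out = n))
}

# two Gaussian blobs plus one optional bridging cell halfway between
makeBlobDataset <- function(nPerBlob = 15, bridge = TRUE, seed = 7) {
  set.seed(seed)
  b1 <- matrix(rnorm(2 * nPerBlob, sd = 0.4), ncol = 2)
  b2 <- matrix(rnorm(2 * nPerBlob, sd = 0.4), ncol = 2)
  b2[, 1] <- b2[, 1] + 5
  emb <- rbind(b1, b2)
  clone <- c(rep("A", nPerBlob), rep("B", nPerBlob))
  if (bridge) {
    emb <- rbind(emb, c(2.5, 0))
    clone <- c(clone, NA)
  }
  n <- nrow(emb)
  expr <- matrix(abs(rnorm(3 * n)), 3, n,
                 dimnames = list(paste0("g", 1:3), paste0("c", seq_len(n))))
  CellDataset(expr, emb, cloneId = clone)
}

# independent brute-force helpers (oracles) ---------------------------------

# Dijkstra from one source over a weighted adjacency matrix (dense, Inf = no
# edge); deliberately naive
oracleDijkstra <- function(W, source) {
  n <- nrow(W)
  dist <- rep(Inf, n)
  dist[source] <- 0
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which(!done & dist == min(dist[!done]))[1]
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (v in which(is.finite(W[u, ]))) {
      if (dist[u] + W[u, v] < dist[v]) dist[v] <- dist[u] + W[u, v]
    }
  }
  dist
}

# brute-force BH step-up
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# weighted covariance trace via explicit loops
oraclePlasticity <- function(X, w) {
  w <- w / sum(w)
  mu <- rep(0, ncol(X))
  for (i in seq_len(nrow(X))) mu <- mu + w[i] * X[i, ]
  v <- 0
  for (i in seq_len(nrow(X))) v <- v + w[i] * sum((X[i, ] - mu)^2)
  v
}

# nested-OLS ANCOVA interaction F-test for hard two-group labels
oracleAncovaF <- function(y, t, group) {
  full <- lm(y ~ group + t + group:t)
  null <- lm(y ~ t)
  a <- anova(null, full)
  list(F = a$F[2], p = a$`Pr(>F)`[2])
}

# Frozen independent LP optima (scipy.optimize.linprog, HiGHS) for the 30
# instances generated below under set.seed(1721).
SCIPY_EMD <- c(
  0.191327564586, 0.034923416548, 0.177852062824, 0.196519098968,
  0.092873889420, 0.096161909169, 0.171233493827, 0.171336174324,
  0.114413065805, 0.116619759185, 0.025320312188, 0.062055834319,
  0.135112083371, 0.117126607879, 0.047943891334, 0.116987672617,
  0.138707332004, 0.104473040844, 0.153064558831, 0.219180984184,
  0.198431178134, 0.197080416933, 0.122371547356, 0.045581158248,
  0.179731559610, 0.139442819655, 0.174383756912, 0.075822832074,
  0.072666420512, 0.096670734934)

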