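# Shared fixtures and independent oracles used across the suite.

# small deterministic count fixture: 3 genes x 2 samples
tiny_counts <- function() {
  m <- matrix(c(0L, 5L, 10L, 1L, 2L, 3L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m
}

tiny_meta <- function() {
  data.frame(sample_id = c("s1", "s2"), tissue_group = c("N", "NAT"),
             sex = c("F", "M"), age = c(40, 50), lt_status = c("LT-", "LT+"),
             patient_id = c("p1", "p2"), stringsAsFactors = FALSE)
}

# brute-force BH step-up: explicit sort + cumulative min from the tail
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# O(n^3) UPGMA oracle: explicit average-linkage agglomeration over a
# Euclidean distance matrix; returns sorted merge heights
upgma_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1L, n)
  heights <- numeric(0)
  while (length(active) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1L)) {
        dij <- d[active[i], active[j]]
        if (dij < best_d) { best_d <- dij; best <- c(active[j], active[i]) }
      }
    }
    heights <- c(heights, best_d)
    a <- best[1L]; b <- best[2L]
    # unweighted average linkage update
    for (k in setdiff(active, best)) {
      d[a, k] <- d[k, a] <- (sizes[a] * d[a, k] + sizes[b] * d[b, k]) /
        (sizes[a] + sizes[b])
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  sort(heights)
}

# NB log-likelihood (fixed dispersion alpha, log link, offset) for the LRT oracle
nb_loglik <- function(beta, y, X, offset, alpha) {
  mu <- exp(pmin(pmax(X %*% beta + offset, -30), 30))
  size <- 1 / alpha
  sum(stats::dnbinom(y, mu = mu, size = size, log = TRUE))
}

# direct-maximization LRT p-value for a two-column design (intercept + group)
lrt_pvalue <- function(y, X, offset, alpha) {
  full <- stats::optim(c(log(mean(y) + 0.5), 0), function(b)
    -nb_loglik(b, y, X, offset, alpha), method = "BFGS")
  X0 <- matrix(1, length(y), 1L)
  null <- stats::optimize(function(b0) -nb_loglik(b0, y, X0, offset, alpha),
                          interval = c(-20, 20))
  stat <- max(0, 2 * (null$objective - full$value))
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

# region counts by explicit enumeration over the union (overlap oracle)
overlap_brute <- function(ids) {
  universe <- unique(unlist(ids))
  key <- vapply(universe, function(g) {
    paste(names(ids)[vapply(ids, function(s) g %in% s, logical(1L))],
          collapse = "&")
  }, character(1L))
  table(key)
}

extdata <- function(f) {
  system.file("extdata", f, package = "natrajectory", mustWork = TRUE)
}
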