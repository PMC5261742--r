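BASES <- c("A", "C", "G", "T")
TAXA <- c("A1", "A2", "S1", "S2", "OUT")

#' GTR + discrete-Gamma substitution model
#'
#' General time-reversible rate matrix with stationary base frequencies `pi`,
#' symmetric exchangeabilities (order AC, AG, AT, CG, CT, GT) and
#' Gamma-distributed among-site rate variation discretized into `k`
#' equal-probability categories (category rates are the within-category means,
#' so the mean rate is exactly 1). `alpha = Inf` or `k = 1` collapses to a
#' single rate, i.e. plain GTR.
#'
#' @param pi Base frequencies (A, C, G, T), summing to 1.
#' @param exch Six positive exchangeabilities (default all 1).
#' @param alpha Gamma shape (> 0, or `Inf` for no rate variation).
#' @param k Number of discrete rate categories (default 4).
#' @return list of class `substitution_model` with the rate-matrix
#'   eigen-decomposition (`V`, `Vinv`, `lambda`) and category `rates`.
#' @export
substitution_model <- function(pi = rep(0.25, 4), exch = rep(1, 6),
                               alpha = 1, k = 4) {
  stopifnot(length(pi) == 4, length(exch) == 6, all(exch > 0), alpha > 0,
            k >= 1)
  if (abs(sum(pi) - 1) > 1e-9) stop("pi must sum to 1")
  if (any(pi <= 0)) stop("pi must be positive")
  pi <- unname(pi)
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- exch[c(1, 2, 3, 4, 5, 6)]
  # fill order: (2,1)=AC,(3,1)=AG,(4,1)=AT,(3,2)=CG,(4,2)=CT,(4,3)=GT
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))   # normalize to 1 expected change per unit time
  Q <- Q / scale
  # reversible Q: symmetrize with sqrt(pi) for a stable eigen-decomposition
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- diag(1 / sp) %*% eg$vectors
  Vinv <- t(eg$vectors) %*% diag(sp)
  structure(list(pi = pi, exch = unname(exch), alpha = alpha, k = as.integer(k),
                 Q = Q, V = V, Vinv = Vinv, lambda = eg$values,
                 rates = discrete_gamma_rates(alpha, k)),
            class = "substitution_model")
}

# equal-probability discrete Gamma categories, each represented by its
# within-category mean rate (overall mean exactly 1)
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1 || is.infinite(alpha)) return(1)
  qb <- qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  k * diff(pgamma(c(0, qb, Inf), shape = alpha + 1, rate = alpha))
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution_model: GTR+Gamma(alpha=%.3g, k=%d)\n  pi = %s\n",
              x$alpha, x$k, paste(sprintf("%.3f", x$pi), collapse = " ")))
  invisible(x)
}

# alignment columns -> compressed site patterns for the C++ pruning code
aln_patterns <- function(aln) {
  st <- matrix(match(aln$seqs, BASES), nrow = 5)
  st[is.na(st)] <- 0L           # N / gap
  st <- st - 1L                 # 0..3, -1 missing
  key <- colSums((st + 1L) * 5L^(0:4))   # base-5 pattern code
  u <- which(!duplicated(key))
  w <- tabulate(match(key, key[u]), nbins = length(u))
  list(tips = t(st[, u, drop = FALSE]), weights = as.numeric(w))
}

#' GTR+Gamma log-likelihood of a five-taxon alignment on a fixed tree
#'
#' Felsenstein pruning over the discrete-Gamma rate mixture; columns
#' containing N or gaps contribute through marginalization.
#'
#' @param aln A [assemble_alignment()] result (or any list with a 5 x L
#'   character matrix `seqs` with rows A1, A2, S1, S2, OUT).
#' @param topology Topology index 1..15 (see [topologies5()]) or a
#'   `tree_result`.
#' @param lengths Branch lengths in postorder edge order (7 edges), >= 0.
#' @param model A [substitution_model()].
#' @return log-likelihood (double).
#' @export
gtr_gamma_loglik <- function(aln, topology, lengths, model) {
  stopifnot(inherits(model, "substitution_model"))
  topo <- resolve_topology(topology)
  if (length(lengths) != length(topo$parent))
    stop("need ", length(topo$parent), " branch lengths")
  if (any(!is.finite(lengths)) || any(lengths < 0))
    stop("branch lengths must be finite and >= 0")
  pat <- aln_patterns(aln)
  cpp_loglik(pat$tips, pat$weights, topo$parent, topo$child,
             pmax(lengths, 1e-12), topo$root, model$pi, model$V, model$Vinv,
             model$lambda, model$rates)
}
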