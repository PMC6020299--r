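# Reversible substitution models for likelihood computation and sequence
# simulation. A model is a symmetric exchangeability matrix S plus
# stationary frequencies pi; the rate matrix Q = S diag(pi) (diagonal set so
# rows sum to zero) is rescaled to one expected substitution per unit time
# (-sum_i pi_i Q_ii = 1). Reversibility (detailed balance) holds by
# construction; transition probabilities come from the symmetric
# eigendecomposition of diag(pi)^(1/2) Q diag(pi)^(-1/2). Optional discrete
# gamma rate heterogeneity uses K equal-weight categories with mean bin
# rates.

NT_STATES <- c("A", "C", "G", "T")
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build a reversible substitution model
#'
#' @param type One of "jc" (Jukes-Cantor), "gtr" (general time reversible,
#'   nucleotide), "poisson_aa" (equal-rate amino acid), or "custom".
#' @param rates For "gtr": the 6 exchangeabilities in the order AC, AG, AT,
#'   CG, CT, GT. For "custom": a symmetric k x k exchangeability matrix with
#'   non-negative off-diagonal entries (dimnames give the state alphabet).
#' @param freqs Stationary frequencies (must sum to 1); defaults to uniform.
#' @param gamma_shape Optional shape of a discrete-gamma rate mixture.
#' @param n_cat Number of gamma categories (default 4).
#' @return An object of class `lux_submodel`.
#' @export
substitution_model <- function(type = c("jc", "gtr", "poisson_aa", "custom"),
                               rates = NULL, freqs = NULL,
                               gamma_shape = NULL, n_cat = 4) {
  type <- match.arg(type)
  if (type == "jc") {
    states <- NT_STATES
    S <- matrix(1, 4, 4, dimnames = list(states, states))
    freqs <- freqs %||% rep(0.25, 4)
  } else if (type == "gtr") {
    states <- NT_STATES
    rates <- rates %||% rep(1, 6)
    if (length(rates) != 6 || any(rates < 0)) {
      abort("gtr needs 6 non-negative exchangeabilities (AC AG AT CG CT GT)")
    }
    S <- matrix(0, 4, 4, dimnames = list(states, states))
    S[lower.tri(S)] <- rates[c(1, 2, 3, 4, 5, 6)]
    # lower.tri fills column-wise: (2,1)=AC,(3,1)=AG,(4,1)=AT,(3,2)=CG,
    # (4,2)=CT,(4,3)=GT — matches the stated order
    S <- S + t(S)
    freqs <- freqs %||% rep(0.25, 4)
  } else if (type == "poisson_aa") {
    states <- AA_STATES
    S <- matrix(1, 20, 20, dimnames = list(states, states))
    freqs <- freqs %||% rep(1 / 20, 20)
  } else {
    if (!is.matrix(rates)) abort("custom model needs a rates matrix")
    if (!isTRUE(all.equal(rates, t(rates), tolerance = 1e-10))) {
      abort("exchangeability matrix must be symmetric (reversible model)")
    }
    if (any(rates[row(rates) != col(rates)] < 0)) {
      abort("off-diagonal exchangeabilities must be >= 0")
    }
    S <- rates
    states <- rownames(S) %||% as.character(seq_len(nrow(S)))
    freqs <- freqs %||% rep(1 / nrow(S), nrow(S))
  }
  k <- length(states)
  if (length(freqs) != k || any(freqs <= 0)) {
    abort("freqs must be positive and match the alphabet size")
  }
  freqs <- freqs / sum(freqs)
  diag(S) <- 0
  Q <- S %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(states, states)
  # symmetric form for well-conditioned exponentials
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  cat_rates <- 1
  cat_weights <- 1
  if (!is.null(gamma_shape)) {
    stopifnot(gamma_shape > 0, n_cat >= 1)
    cat_rates <- discrete_gamma_rates(gamma_shape, n_cat)
    cat_weights <- rep(1 / n_cat, n_cat)
  }
  structure(list(
    type = type,
    alphabet = if (k == 4) "nucleotide" else "amino-acid",
    states = states, pi = freqs, Q = Q,
    eig_values = eig$values, eig_vectors = eig$vectors, d = d,
    gamma_shape = gamma_shape, cat_rates = cat_rates,
    cat_weights = cat_weights
  ), class = "lux_submodel")
}

# mean rate within each of K equal-probability gamma bins (shape = rate =
# alpha so the mean is 1)
discrete_gamma_rates <- function(alpha, K) {
  if (K == 1) return(1)
  b <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  r <- K * (pgamma(b[-1], shape = alpha + 1, rate = alpha) -
              pgamma(b[-(K + 1)], shape = alpha + 1, rate = alpha))
  r / mean(r) * 1 # guard tiny numeric drift; mean(r) == 1 analytically
}

#' @export
print.lux_submodel <- function(x, ...) {
  cat("<lux_submodel> ", x$type, " (", x$alphabet, ", ",
      length(x$states), " states)", sep = "")
  if (!is.null(x$gamma_shape)) {
    cat(" + gamma(", format(x$gamma_shape), ") x ",
        length(x$cat_rates), sep = "")
  }
  cat("\n")
  invisible(x)
}

# transition probability matrix P(t) for one branch length t (expected
# substitutions per site)
model_pmat <- function(model, t) {
  t <- max(t, 0)
  ev <- exp(model$eig_values * t)
  V <- model$eig_vectors
  P <- diag(1 / model$d) %*% (V %*% (ev * t(V))) %*% diag(model$d)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Read an amino-acid exchangeability matrix in PAML dialect
#'
#' The format is a lower-triangular block of 19 rows of exchangeabilities
#' followed by a line of 20 stationary frequencies (whitespace separated;
#' blank lines ignored). State order is the standard PAML amino-acid order.
#'
#' @param path Path to the rate-matrix file.
#' @param gamma_shape,n_cat Optional discrete-gamma mixture.
#' @return A `lux_submodel`.
#' @export
read_paml_model <- function(path, gamma_shape = NULL, n_cat = 4) {
  toks <- scan(path, what = double(), quiet = TRUE, comment.char = "#")
  need <- 190 + 20
  if (length(toks) < need) {
    abort("PAML rate file must hold 190 exchangeabilities + 20 frequencies")
  }
  S <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  k <- 1
  for (i in 2:20) {
    for (j in 1:(i - 1)) {
      S[i, j] <- S[j, i] <- toks[k]
      k <- k + 1
    }
  }
  freqs <- toks[k:(k + 19)]
  substitution_model("custom", rates = S, freqs = freqs,
                     gamma_shape = gamma_shape, n_cat = n_cat)
}
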