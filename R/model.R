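AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# md5 of the shipped Dayhoff data file; guards against silent edits
.DAYHOFF_MD5 <- "bc73d24f548adb2db3bcaf118331200b"

#' Dayhoff amino-acid substitution model
#'
#' Builds a time-reversible 20-state substitution model from the published
#' Dayhoff (1978) PAM-based exchangeabilities and equilibrium frequencies,
#' shipped with the package as a plain-text data file whose checksum is
#' verified at load time. The instantaneous rate matrix Q is scaled so that
#' the expected number of substitutions per unit branch length equals 1.
#'
#' @param freqs Optional replacement equilibrium frequencies (length 20,
#'   ordered as `ARNDCQEGHILKMFPSTWYV`); defaults to the Dayhoff frequencies.
#' @return An object of class `aa_model` with elements `name`,
#'   `exchangeabilities` (symmetric 20x20), `freqs`, `Q` (scaled rate
#'   matrix), and a cached spectral decomposition used to compute transition
#'   probabilities.
#' @examples
#' m <- dayhoff_model()
#' range(rowSums(m$Q))  # ~0
#' @export
dayhoff_model <- function(freqs = NULL) {
  path <- system.file("extdata", "dayhoff_model.tsv", package = "palaeoprot")
  if (!nzchar(path)) stop("Dayhoff model data file not found")
  if (!identical(unname(tools::md5sum(path)), .DAYHOFF_MD5))
    stop("Dayhoff model data file failed its checksum")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           row.names = 1, check.names = FALSE)
  R <- as.matrix(tab[AA20, AA20])
  pi0 <- as.numeric(tab["freq", AA20])
  if (is.null(freqs)) freqs <- pi0
  stopifnot(length(freqs) == 20, all(freqs > 0))
  freqs <- freqs / sum(freqs)
  aa_model("Dayhoff", R, freqs)
}

#' Construct a reversible amino-acid model from exchangeabilities
#'
#' @param name Model name.
#' @param exchangeabilities Symmetric non-negative 20x20 matrix (diagonal
#'   ignored), rows/cols ordered as `ARNDCQEGHILKMFPSTWYV`.
#' @param freqs Equilibrium frequencies (length 20, positive; normalised).
#' @return An `aa_model` object (see [dayhoff_model()]).
#' @export
aa_model <- function(name, exchangeabilities, freqs) {
  R <- as.matrix(exchangeabilities)
  stopifnot(identical(dim(R), c(20L, 20L)))
  if (max(abs(R - t(R))) > 1e-9) stop("exchangeabilities must be symmetric")
  freqs <- as.numeric(freqs)
  freqs <- freqs / sum(freqs)
  Q <- R %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # scale: expected rate = sum_i pi_i * (-Q_ii) = 1
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  # symmetrise for a stable eigendecomposition: B = D^1/2 Q D^-1/2
  d <- sqrt(freqs)
  B <- (d * Q) %*% diag(1 / d)   # rows scaled by d, cols by 1/d
  B <- (B + t(B)) / 2
  es <- eigen(B, symmetric = TRUE)
  structure(list(
    name = name,
    exchangeabilities = R,
    freqs = freqs,
    Q = Q,
    eig = list(values = es$values,
               # P(t) = V diag(exp(l t)) Vinv with V = D^-1/2 U
               V = diag(1 / d) %*% es$vectors,
               Vinv = t(es$vectors) %*% diag(d))
  ), class = "aa_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model An `aa_model`.
#' @param t Branch length (expected substitutions per site), `t >= 0`.
#' @return 20x20 stochastic matrix.
#' @export
transition_prob <- function(model, t) {
  if (t < 0) stop("negative branch length")
  P <- model$eig$V %*% (exp(model$eig$values * t) * model$eig$Vinv)
  # numerical cleanup: clamp tiny negatives
  P[P < 0] <- 0
  dimnames(P) <- list(AA20, AA20)
  P
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("Amino-acid substitution model: %s\n", x$name))
  cat(sprintf("  20 states, mean rate 1.0, pi range [%.4f, %.4f]\n",
              min(x$freqs), max(x$freqs)))
  invisible(x)
}
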