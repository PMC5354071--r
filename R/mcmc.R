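# Bayesian MCMC over tree topology, branch lengths and per-partition rate
# multipliers: single-chain Metropolis-Hastings with NNI topology proposals,
# single-branch and whole-tree multiplicative branch-length proposals, and a
# Dirichlet proposal on the per-partition rate multipliers, which are kept
# at site-weighted mean 1 so that rates and tree length stay identifiable.
# Priors: uniform on topologies, exponential (mean 0.1) on branch lengths,
# flat Dirichlet on the rate simplex.

BL_PRIOR_MEAN <- 0.1

.log_prior <- function(el) {
  sum(stats::dexp(el, rate = 1 / BL_PRIOR_MEAN, log = TRUE))
}

# Dirichlet density/sampler for the rate-multiplier simplex proposal
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}
.ddirichlet_log <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

# Metropolis-Hastings acceptance probability
.mh_alpha <- function(log_post_new, log_post_old, log_hastings = 0)
  min(1, exp(log_post_new - log_post_old + log_hastings))

#' Sample tree space by Metropolis-Hastings MCMC
#'
#' Runs a single-chain sampler over (topology, branch lengths, per-partition
#' rate multipliers). Defaults mirror a standard Bayesian protein-phylogeny
#' protocol: five million generations sampled every 500 with the first 10%
#' discarded as burn-in; scale the generation count down for desk-size
#' problems. The state is recorded at generation 0 and every
#' `sample_interval` generations, so the trace holds
#' `generations / sample_interval + 1` samples.
#'
#' @param aln A `partitioned_alignment`.
#' @param model An `aa_model`.
#' @param generations Number of MCMC generations; must be divisible by
#'   `sample_interval`.
#' @param sample_interval Thinning interval (default 500).
#' @param burn_in_fraction Fraction of samples discarded by downstream
#'   summaries (default 0.10).
#' @param seed Integer seed.
#' @param start_tree Optional start `phylo` (default: NJ tree).
#' @param sample_rates Sample per-partition rate multipliers (default: yes
#'   when there is more than one partition).
#' @return An `mcmc_trace`: `generation`, `lnl`, `tree_length`, `rates`
#'   (matrix), `trees` (`multiPhylo`), plus the run settings.
#' @export
mcmc_sample <- function(aln, model, generations = 5e6, sample_interval = 500,
                        burn_in_fraction = 0.10, seed = 1, start_tree = NULL,
                        sample_rates = NULL) {
  if (generations < sample_interval || generations %% sample_interval != 0)
    stop("generations must be a positive multiple of sample_interval")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must be in [0, 1)")
  set.seed(seed)
  enc <- encode_alignment(aln)
  nparts <- length(enc$parts)
  if (is.null(sample_rates)) sample_rates <- nparts > 1L
  if (is.null(start_tree)) start_tree <- nj_start_tree(aln, model)
  start_tree$edge.length[start_tree$edge.length < BL_MIN] <- BL_MIN
  tf <- tree_eval_form(start_tree, enc$taxa)
  # tip order is invariant under the NNI move, so reorder patterns once
  for (k in seq_len(nparts))
    enc$parts[[k]]$states <- enc$parts[[k]]$states[tf$tip.label, , drop = FALSE]
  sites <- vapply(enc$parts, `[[`, integer(1), "nsites")
  wts <- sites / sum(sites)
  rates <- rep(1, nparts)  # site-weighted mean kept at 1
  part_lnl <- vapply(seq_len(nparts), function(k)
    .part_lnl(tf, enc$parts[[k]], model, rates[k]), numeric(1))
  lnl <- sum(part_lnl)
  lp <- .log_prior(tf$el)

  nsamp <- generations %/% sample_interval + 1L
  tr_gen <- integer(nsamp); tr_lnl <- numeric(nsamp)
  tr_tl <- numeric(nsamp); tr_rates <- matrix(NA_real_, nsamp, nparts)
  trees <- vector("list", nsamp)
  record <- function(i, gen) {
    tr_gen[i] <<- gen; tr_lnl[i] <<- lnl; tr_tl[i] <<- sum(tf$el)
    tr_rates[i, ] <<- rates
    phy <- tf$phy
    trees[[i]] <<- phy
  }
  record(1L, 0L)

  all_lnl <- function(tf, r = rates) vapply(seq_len(nparts), function(k)
    .part_lnl(tf, enc$parts[[k]], model, r[k]), numeric(1))

  n_int <- length(internal_edges(tf))
  for (gen in seq_len(generations)) {
    u <- stats::runif(1)
    if (u < 0.30 || (n_int == 0L && u < 0.45)) {
      # multiplicative single-branch proposal
      e <- sample.int(length(tf$el), 1L)
      mult <- exp(1.0 * (stats::runif(1) - 0.5))
      new_el <- tf$el
      new_el[e] <- min(max(tf$el[e] * mult, BL_MIN), BL_MAX)
      tf2 <- tf; tf2$el <- new_el; tf2$phy$edge.length <- new_el
      pl2 <- all_lnl(tf2)
      lp2 <- .log_prior(new_el)
      a <- .mh_alpha(sum(pl2) + lp2, lnl + lp, log(mult))
      if (stats::runif(1) < a) {
        tf <- tf2; part_lnl <- pl2; lnl <- sum(pl2); lp <- lp2
      }
    } else if (u < 0.45) {
      # whole-tree scale proposal (decorrelates total tree length)
      mult <- exp(0.5 * (stats::runif(1) - 0.5))
      new_el <- pmin(pmax(tf$el * mult, BL_MIN), BL_MAX)
      tf2 <- tf; tf2$el <- new_el; tf2$phy$edge.length <- new_el
      pl2 <- all_lnl(tf2)
      lp2 <- .log_prior(new_el)
      a <- .mh_alpha(sum(pl2) + lp2, lnl + lp, length(tf$el) * log(mult))
      if (stats::runif(1) < a) {
        tf <- tf2; part_lnl <- pl2; lnl <- sum(pl2); lp <- lp2
      }
    } else if (u < 0.75 || !sample_rates) {
      # NNI topology proposal (symmetric)
      ie <- internal_edges(tf)
      e <- ie[sample.int(length(ie), 1L)]
      ce <- edges_by_parent(tf)
      vkids <- ce[[tf$edge[e, 2L]]]
      sibs <- setdiff(ce[[tf$edge[e, 1L]]], e)
      if (length(vkids) == 2L && length(sibs) >= 1L) {
        cand <- sample.int(2L, 1L)
        nni <- list(e = e, s_edge = sibs[1L], moved = vkids[cand],
                    kept = vkids[3L - cand], t = tf$el[e])
        tf2 <- apply_nni(tf, nni)
        pl2 <- all_lnl(tf2)
        lp2 <- .log_prior(tf2$el)
        a <- .mh_alpha(sum(pl2) + lp2, lnl + lp)
        if (stats::runif(1) < a) {
          tf <- tf2; part_lnl <- pl2; lnl <- sum(pl2); lp <- lp2
          n_int <- length(internal_edges(tf))
        }
      }
    } else {
      # Dirichlet proposal on the rate simplex (flat Dirichlet prior)
      conc <- 300
      p <- rates * wts
      p2 <- .rdirichlet(conc * p)
      if (all(p2 > 0)) {
        r2 <- p2 / wts
        pl2 <- all_lnl(tf, r2)
        lh <- .ddirichlet_log(p, conc * p2) - .ddirichlet_log(p2, conc * p)
        a <- .mh_alpha(sum(pl2) + lp, lnl + lp, lh)
        if (stats::runif(1) < a) {
          rates <- r2; part_lnl <- pl2; lnl <- sum(pl2)
        }
      }
    }
    if (gen %% sample_interval == 0L)
      record(gen %/% sample_interval + 1L, gen)
  }
  class(trees) <- "multiPhylo"
  structure(list(generation = tr_gen, lnl = tr_lnl, tree_length = tr_tl,
                 rates = tr_rates, trees = trees,
                 sample_interval = sample_interval,
                 burn_in_fraction = burn_in_fraction,
                 generations = generations, seed = seed),
            class = "mcmc_trace")
}

#' Post-burn-in portion of an MCMC trace
#' @param trace An `mcmc_trace`.
#' @return The trace with the first `burn_in_fraction` of samples removed.
#' @export
discard_burnin <- function(trace) {
  n <- length(trace$generation)
  drop <- seq_len(floor(n * trace$burn_in_fraction))
  if (!length(drop)) return(trace)
  trace$generation <- trace$generation[-drop]
  trace$lnl <- trace$lnl[-drop]
  trace$tree_length <- trace$tree_length[-drop]
  trace$rates <- trace$rates[-drop, , drop = FALSE]
  trace$trees <- trace$trees[-drop]
  class(trace$trees) <- "multiPhylo"
  trace
}

#' Effective sample size of a trace
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated
#' by Geyer's initial positive sequence criterion. A constant trace has no
#' information and reports ESS 1 with a warning.
#'
#' @param x Numeric vector of at least 10 post-burn-in samples.
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples for an ESS estimate")
  if (stats::var(x) == 0) {
    warning("constant trace; ESS reported as 1")
    return(1)
  }
  rho <- stats::acf(x, lag.max = n - 2L, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  s <- 0
  m <- 0L
  while (2L * m + 2L <= length(rho)) {
    g <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (g <= 0) break
    s <- s + g
    m <- m + 1L
  }
  max(1, n / (1 + 2 * s))
}

#' MCMC convergence diagnostics
#'
#' Reports the ESS of the log-likelihood, total tree length and every
#' sampled rate multiplier after burn-in, flagging parameters at or below
#' `threshold`.
#'
#' @param trace An `mcmc_trace`.
#' @param threshold ESS threshold (default 200).
#' @return data.frame: parameter, ess, ok.
#' @export
mcmc_diagnostics <- function(trace, threshold = 200) {
  post <- discard_burnin(trace)
  vals <- c(list(lnl = post$lnl, tree_length = post$tree_length),
            stats::setNames(lapply(seq_len(ncol(post$rates)),
                                   function(k) post$rates[, k]),
                            paste0("rate_", seq_len(ncol(post$rates)))))
  keep <- vapply(vals, function(v) stats::var(v) > 0, logical(1))
  vals <- vals[keep]
  out <- data.frame(parameter = names(vals),
                    ess = vapply(vals, ess, numeric(1)),
                    stringsAsFactors = FALSE)
  out$ok <- out$ess > threshold
  if (any(!out$ok))
    warning(sprintf("parameter(s) with ESS <= %d: %s", threshold,
                    paste(out$parameter[!out$ok], collapse = ", ")))
  out
}

#' Posterior probability of a clade
#' @param trace An `mcmc_trace`.
#' @param taxa Tip labels forming the clade (one side of the bipartition).
#' @return Fraction of post-burn-in trees containing the bipartition.
#' @export
clade_posterior <- function(trace, taxa) {
  post <- discard_burnin(trace)
  mean(vapply(post$trees, has_clade, logical(1), taxa = taxa))
}
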