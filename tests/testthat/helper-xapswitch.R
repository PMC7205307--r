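## Shared fixtures for the test suite.  Everything is generated in code.

ref_params <- xap_params()          # canonical bistable reference, c_a = 13
ref_geom <- cell_geometry()         # 1 fL, K_a = 5e-5 M -> Omega ~ 3.01e4

## a simple birth-death network: 0 -> A at `birth`, A -> 0 at `death` per
## molecule; stationary law is Poisson(birth / death)
birth_death_network <- function(birth, death, burst_mean = 1) {
  reaction_network(
    species = "A",
    stoich = matrix(c(1L, -1L), 1, 2),
    reactions = list(
      list(name = "birth", type = "constant", rate = birth,
           burst_mean = burst_mean),
      list(name = "death", type = "linear", rate = death, scale_sp = "A")
    )
  )
}

## random nonnegative states spanning the dynamic range of the model
random_states <- function(n, seed = 1) {
  set.seed(seed)
  cbind(m_a = 10^runif(n, -7, -2),
        p_a = 10^runif(n, -5, 0),
        x_a = 10^runif(n, -3, 4))
}

## chi-squared goodness-of-fit p-value of integer samples against a
## Poisson law with the given mean (tail bins pooled to keep expected
## counts above 5)
poisson_gof_pvalue <- function(samples, lambda) {
  kmax <- max(samples)
  obs <- tabulate(samples + 1L, nbins = kmax + 1L)
  exp_p <- stats::dpois(0:kmax, lambda)
  exp_p[kmax + 1L] <- exp_p[kmax + 1L] + stats::ppois(kmax, lambda,
                                                      lower.tail = FALSE)
  exp_n <- exp_p * length(samples)
  ## pool bins with small expected counts
  grp <- cumsum(ifelse(exp_n >= 5, 1, 0))
  grp[grp == 0] <- 1
  obs_g <- tapply(obs, grp, sum)
  exp_g <- tapply(exp_n, grp, sum)
  stat <- sum((obs_g - exp_g)^2 / exp_g)
  stats::pchisq(stat, df = length(obs_g) - 1L, lower.tail = FALSE)
}
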