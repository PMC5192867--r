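# Two plasmids competing for a shared conjugation apparatus (T4SS) in a
# nutrient-limited growing bacterial colony.
#
# Cells sit on a 100 x 100 um periodic lattice (continuous positions,
# overlap allowed, no death).  Plasmid P1 carries the full conjugative
# machinery; P2 is a cheater that has lost those genes and can only be
# mobilised through a co-resident P1's type IV secretion system.  Each tick
# (1 min) a cell takes up to `uptake` nutrient particles from its lattice
# site, grows exponentially at a rate scaled by the uptake fraction and
# slowed by plasmid carriage costs, divides at its division mass (both
# daughters inherit the plasmids), and — once a P1-bearing cell passes 70%
# of its division mass — may conjugate: a single Bernoulli(p1P) draw per
# cell cycle decides whether it will transfer at all, and a pending donor
# retries each tick on one random cell within 1.5 um until a transfer
# lands or the cell divides.

T4_SIZE <- 100L

t4_defaults <- function() list(
  doublingTime = 40,    # minutes, plasmid-free
  p1P = 0.25,           # P(gamma0): chance of conjugating at least once per cycle
  p1Cost = 0.1,         # fractional growth penalty of P1
  p2Cost = 0.05,        # fractional growth penalty of P2
  n0 = 50L,             # initial (founder) cells
  f1 = 0.1,             # initial fraction carrying P1 only
  f2 = 0.1,             # initial fraction carrying P2 only
  nutrient = 100L,      # particles per lattice site
  uptake = 1,           # max particles per cell per tick
  hijack = 0.5,         # P(transfer P2 | donor carries both)
  diffusion = 0,        # per-tick random walk step (um); 0 = off
  inoculum = 20         # side (um) of the central founder square
)

t4_factors <- function() factor_table(
  doublingTime = c(20, 60),
  p1P = c(0, 1),
  p1Cost = c(0, 0.3),
  p2Cost = c(0, 0.3)
)

#' T4SS common-pool model
#'
#' Builds the two-plasmid conjugation simulator as an [sa_model]; declared
#' parameters are the four biological knobs (`doublingTime`, `p1P`,
#' `p1Cost`, `p2Cost`) plus initialization knobs (`n0`, `f1`, `f2`,
#' `nutrient`, `uptake`, `hijack`, `diffusion`).  Each run emits per-tick
#' census counts `free`, `P1`, `P2`, `Both`, `total`.
#'
#' @return An `sa_model` named `"t4ss_pool"`.
#' @export
t4_model <- function() {
  sa_model("t4ss_pool", t4_defaults(), setup = t4_setup,
           factors = t4_factors())
}

# division-mass deviates: normal(1, 0.05) truncated at +/- 3 sd (rejection)
t4_division_mass <- function(n) {
  out <- stats::rnorm(n, 1, 0.05)
  bad <- which(abs(out - 1) > 0.15)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), 1, 0.05)
    bad <- bad[abs(out[bad] - 1) > 0.15]
  }
  out
}

t4_setup <- function(p) {
  d <- t4_defaults()
  miss <- setdiff(names(d), names(p))
  if (length(miss))
    abort_ibmsens("parameter_error",
                  paste("missing parameter(s):", paste(miss, collapse = ", ")))
  num <- vapply(names(d), function(nm) as.numeric(p[[nm]]), numeric(1))
  if (any(!is.finite(num)))
    abort_ibmsens("parameter_error", "all parameters must be finite")
  if (num["doublingTime"] <= 0)
    abort_ibmsens("parameter_error", "doublingTime must be > 0")
  if (num["p1P"] < 0 || num["p1P"] > 1 || num["hijack"] < 0 || num["hijack"] > 1)
    abort_ibmsens("parameter_error", "p1P and hijack are probabilities in [0, 1]")
  if (num["p1Cost"] < 0 || num["p2Cost"] < 0)
    abort_ibmsens("parameter_error", "plasmid costs must be >= 0")
  if (num["f1"] < 0 || num["f2"] < 0 || num["f1"] + num["f2"] > 1)
    abort_ibmsens("parameter_error", "f1, f2 must be >= 0 with f1 + f2 <= 1")

  e <- new.env(parent = emptyenv())
  e$G <- num["doublingTime"]; e$p1P <- num["p1P"]
  e$c1 <- num["p1Cost"]; e$c2 <- num["p2Cost"]
  e$u <- num["uptake"]; e$hijack <- num["hijack"]; e$diff <- num["diffusion"]
  n0 <- as.integer(round(num["n0"]))
  half <- min(T4_SIZE, max(1, num["inoculum"])) / 2
  ctr <- T4_SIZE / 2
  e$x <- stats::runif(n0, ctr - half, ctr + half)
  e$y <- stats::runif(n0, ctr - half, ctr + half)
  e$dmass <- t4_division_mass(n0)
  e$mass <- e$dmass * stats::runif(n0, 0.5, 0.99)
  n1 <- as.integer(round(num["f1"] * n0)); n2 <- as.integer(round(num["f2"] * n0))
  who <- sample.int(n0, n1 + n2)
  e$p1 <- integer(n0); e$p2 <- integer(n0)
  e$p1[who[seq_len(n1)]] <- 1L
  if (n2 > 0) e$p2[who[n1 + seq_len(n2)]] <- 1L
  e$resolved <- logical(n0); e$pending <- logical(n0)
  e$nutrient <- rep(as.numeric(max(0, round(num["nutrient"]))),
                    T4_SIZE * T4_SIZE)
  e$consumed <- 0
  e$tick <- 0L
  list(run = function(ticks) t4_run(e, ticks),
       state = function() list(
         cells = data.frame(x = e$x, y = e$y, mass = e$mass, dmass = e$dmass,
                            p1 = e$p1, p2 = e$p2, pending = e$pending,
                            resolved = e$resolved),
         nutrient = e$nutrient, consumed = e$consumed))
}

t4_site <- function(x, y) floor(x) * T4_SIZE + floor(y) + 1

#' Census of plasmid states
#'
#' Exact partition of a population by plasmid carriage: `(0,0)` free,
#' `(1,0)` P1 only, `(0,1)` P2 only, `(1,1)` both.
#'
#' @param p1,p2 0/1 vectors of plasmid states (equal length).
#' @return Named numeric vector `free`, `P1`, `P2`, `Both`, `total`.
#' @export
t4_census <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  c(free = sum(p1 == 0 & p2 == 0),
    P1 = sum(p1 == 1 & p2 == 0),
    P2 = sum(p1 == 0 & p2 == 1),
    Both = sum(p1 == 1 & p2 == 1),
    total = length(p1))
}

#' Conjugation eligibility
#'
#' A cell can act as a donor once it carries P1 (the T4SS genes) and its
#' mass has reached 70% of its division mass (inclusive).
#'
#' @param p1 0/1 plasmid-P1 state.
#' @param mass,division_mass Current and division mass.
#' @return Logical (vectorised).
#' @export
t4_eligible <- function(p1, mass, division_mass) {
  p1 == 1 & mass >= 0.70 * division_mass
}

t4_run <- function(e, ticks) {
  stopifnot(ticks >= 1)
  out <- matrix(0, ticks, 5,
                dimnames = list(NULL, c("free", "P1", "P2", "Both", "total")))
  for (t in seq_len(ticks)) {
    n <- length(e$x)
    # uptake: shuffled order, each cell takes up to u from its site
    site <- t4_site(e$x, e$y)
    ord <- sample.int(n)
    so <- site[ord]
    prior <- (stats::ave(rep(e$u, n), so, FUN = cumsum)) - e$u
    got <- pmin(pmax(e$nutrient[so] - prior, 0), e$u)
    phi <- numeric(n)
    phi[ord] <- if (e$u > 0) got / e$u else 0
    taken <- rowsum(got, so)
    sites_u <- as.integer(rownames(taken))
    e$nutrient[sites_u] <- e$nutrient[sites_u] - taken[, 1]
    e$consumed <- e$consumed + sum(got)
    # growth: exponential, slowed by plasmid costs, capped at division mass
    geff <- e$G * (1 + e$p1 * e$c1 + e$p2 * e$c2)
    e$mass <- pmin(e$mass * exp(phi * log(2) / geff), e$dmass)
    # optional diffusion
    if (e$diff > 0) {
      h <- stats::runif(n, 0, 2 * pi)
      e$x <- (e$x + e$diff * cos(h)) %% T4_SIZE
      e$y <- (e$y + e$diff * sin(h)) %% T4_SIZE
    }
    # division: split at division mass, daughters inherit plasmids,
    # fresh division-mass deviates, conjugation flags reset
    div <- which(e$mass >= e$dmass)
    if (length(div)) {
      nd <- length(div)
      half <- e$mass[div] / 2
      e$dmass[div] <- t4_division_mass(nd)
      e$mass[div] <- half
      e$resolved[div] <- FALSE; e$pending[div] <- FALSE
      h <- stats::runif(nd, 0, 2 * pi)
      e$x <- c(e$x, (e$x[div] + 0.5 * cos(h)) %% T4_SIZE)
      e$y <- c(e$y, (e$y[div] + 0.5 * sin(h)) %% T4_SIZE)
      e$mass <- c(e$mass, half)
      e$dmass <- c(e$dmass, t4_division_mass(nd))
      e$p1 <- c(e$p1, e$p1[div]); e$p2 <- c(e$p2, e$p2[div])
      e$resolved <- c(e$resolved, logical(nd))
      e$pending <- c(e$pending, logical(nd))
    }
    # conjugation: one Bernoulli(p1P) per cycle at first eligibility;
    # pending donors try one random neighbour within 1.5 um per tick
    elig <- which(t4_eligible(e$p1, e$mass, e$dmass) & !e$resolved)
    if (length(elig)) {
      e$pending[elig] <- stats::runif(length(elig)) < e$p1P
      e$resolved[elig] <- TRUE
    }
    donors <- which(e$pending)
    if (length(donors)) {
      donors <- donors[sample.int(length(donors))]
      bins <- split(seq_along(e$x), t4_site(e$x, e$y))
      for (dn in donors) {
        bx <- floor(e$x[dn]); by <- floor(e$y[dn])
        keys <- as.character(outer((bx + -2:2) %% T4_SIZE * T4_SIZE,
                                   (by + -2:2) %% T4_SIZE + 1, "+"))
        cand <- unlist(bins[keys], use.names = FALSE)
        cand <- cand[cand != dn]
        if (!length(cand)) next
        dx <- abs(e$x[cand] - e$x[dn]); dx <- pmin(dx, T4_SIZE - dx)
        dy <- abs(e$y[cand] - e$y[dn]); dy <- pmin(dy, T4_SIZE - dy)
        cand <- cand[dx * dx + dy * dy <= 1.5^2]
        if (!length(cand)) next
        tgt <- if (length(cand) == 1L) cand else sample(cand, 1L)
        q <- if (e$p1[dn] == 1L && e$p2[dn] == 1L) {
          if (stats::runif(1) < e$hijack) "p2" else "p1"
        } else "p1"
        if (e[[q]][tgt] == 0L) {           # transfer: recipient gains q
          e[[q]][tgt] <- 1L
          e$pending[dn] <- FALSE
        }
      }
    }
    e$tick <- e$tick + 1L
    out[t, ] <- t4_census(e$p1, e$p2)
  }
  cbind(data.frame(tick = e$tick - ticks + seq_len(ticks)), as.data.frame(out))
}
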