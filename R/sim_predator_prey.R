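# Wolf-sheep-grass predator-prey individual-based model.
#
# Wolves and sheep live on a 50 x 50 periodic continuous space; grass grows
# on the underlying unit grid.  Each tick every animal turns to a random
# heading, advances one unit and pays one energy unit; sheep graze the
# grown grass patch they stand on (+sheepgainfromfood, patch then regrows
# after grassregrowthtime ticks), wolves eat one random sheep sharing their
# unit patch (+wolfgainfromfood); animals reproduce with probability
# rate/100 (energy split evenly with the offspring) and die when energy
# drops to zero or below.  Phases run synchronously over the population
# with randomised order wherever animals contend for the same resource.

pp_defaults <- function() list(
  initialnumberofwolves = 50L,
  initialnumberofsheep = 100L,
  wolfgainfromfood = 20,
  wolfreproduce = 5,
  sheepgainfromfood = 4,
  sheepreproduce = 4,
  grassregrowthtime = 30L
)

pp_factors <- function() factor_table(
  initialnumberofwolves = c(10, 100),
  initialnumberofsheep = c(20, 200),
  wolfgainfromfood = c(10, 40),
  wolfreproduce = c(2, 10),
  sheepgainfromfood = c(2, 8),
  sheepreproduce = c(2, 10),
  grassregrowthtime = c(10, 60)
)

PP_SIZE <- 50L

#' Predator-prey model
#'
#' Builds the wolf-sheep-grass simulator as an [sa_model]: declared
#' parameters are the seven classic knobs (initial populations, energy
#' gains, reproduction percentages, grass regrowth time); each run emits
#' per-tick counts `wolves`, `sheep`, `grass`.  Initial energies are
#' uniform on `[0, 2 x gain]` and half the patches start grown, following
#' the standard wolf-sheep-predation conventions.
#'
#' @return An `sa_model` named `"predator_prey"`.
#' @export
pp_model <- function() {
  sa_model("predator_prey", pp_defaults(), setup = pp_setup,
           factors = pp_factors())
}

pp_setup <- function(p) {
  d <- pp_defaults()
  miss <- setdiff(names(d), names(p))
  if (length(miss))
    abort_ibmsens("parameter_error",
                  paste("missing parameter(s):", paste(miss, collapse = ", ")))
  num <- vapply(names(d), function(nm) as.numeric(p[[nm]]), numeric(1))
  if (any(!is.finite(num)) || any(num < 0))
    abort_ibmsens("parameter_error", "all parameters must be finite and >= 0")
  if (num["wolfreproduce"] > 100 || num["sheepreproduce"] > 100)
    abort_ibmsens("parameter_error", "reproduction rates are percentages in [0, 100]")

  e <- new.env(parent = emptyenv())
  e$wgain <- num["wolfgainfromfood"]; e$sgain <- num["sheepgainfromfood"]
  e$wrep <- num["wolfreproduce"] / 100; e$srep <- num["sheepreproduce"] / 100
  e$regrow <- max(0L, as.integer(round(num["grassregrowthtime"])))
  nw <- as.integer(round(num["initialnumberofwolves"]))
  ns <- as.integer(round(num["initialnumberofsheep"]))
  e$wx <- stats::runif(nw, 0, PP_SIZE); e$wy <- stats::runif(nw, 0, PP_SIZE)
  e$we <- stats::runif(nw, 0, 2 * e$wgain)
  e$sx <- stats::runif(ns, 0, PP_SIZE); e$sy <- stats::runif(ns, 0, PP_SIZE)
  e$se <- stats::runif(ns, 0, 2 * e$sgain)
  npatch <- PP_SIZE * PP_SIZE
  grown <- stats::runif(npatch) < 0.5
  e$countdown <- ifelse(grown, 0L,
                        sample.int(max(1L, e$regrow), npatch, replace = TRUE))
  e$tick <- 0L
  list(run = function(ticks) pp_run(e, ticks),
       state = function() list(
         sheep = data.frame(x = e$sx, y = e$sy, energy = e$se),
         wolves = data.frame(x = e$wx, y = e$wy, energy = e$we),
         countdown = e$countdown))
}

pp_patch <- function(x, y) floor(x) * PP_SIZE + floor(y) + 1

pp_run <- function(e, ticks) {
  stopifnot(ticks >= 1)
  out <- matrix(0, ticks, 3, dimnames = list(NULL, c("wolves", "sheep", "grass")))
  for (t in seq_len(ticks)) {
    ns <- length(e$sx); nw <- length(e$wx)
    # move: random heading, unit step, periodic wrap, -1 energy
    if (ns > 0) {
      h <- stats::runif(ns, 0, 2 * pi)
      e$sx <- (e$sx + cos(h)) %% PP_SIZE; e$sy <- (e$sy + sin(h)) %% PP_SIZE
      e$se <- e$se - 1
    }
    if (nw > 0) {
      h <- stats::runif(nw, 0, 2 * pi)
      e$wx <- (e$wx + cos(h)) %% PP_SIZE; e$wy <- (e$wy + sin(h)) %% PP_SIZE
      e$we <- e$we - 1
    }
    # graze: one sheep (random order) per grown patch
    if (ns > 0) {
      pid <- pp_patch(e$sx, e$sy)
      ord <- sample.int(ns)
      sel <- e$countdown[pid[ord]] == 0 & !duplicated(pid[ord])
      eaters <- ord[sel]
      if (length(eaters)) {
        e$se[eaters] <- e$se[eaters] + e$sgain
        e$countdown[pid[eaters]] <- e$regrow
      }
    }
    # predation: in each patch the first min(w, s) wolves (shuffled) each
    # eat one distinct random sheep
    eaten <- integer(0)
    if (nw > 0 && length(e$sx) > 0) {
      ns2 <- length(e$sx)
      wp <- pp_patch(e$wx, e$wy); sp <- pp_patch(e$sx, e$sy)
      word <- sample.int(nw); sord <- sample.int(ns2)
      wk <- wp[word]; sk <- sp[sord]
      # within-patch rank in shuffled order (stable sort keeps the shuffle)
      rank_in_patch <- function(keys) {
        o <- order(keys)
        rk <- integer(length(keys))
        rk[o] <- sequence(rle(keys[o])$lengths)
        rk
      }
      cap <- ns2 + nw + 1
      mi <- match(wk * cap + rank_in_patch(wk), sk * cap + rank_in_patch(sk))
      fed <- which(!is.na(mi))
      if (length(fed)) {
        wi <- word[fed]
        e$we[wi] <- e$we[wi] + e$wgain
        eaten <- sord[mi[fed]]
        keep <- setdiff(seq_len(ns2), eaten)
        e$sx <- e$sx[keep]; e$sy <- e$sy[keep]; e$se <- e$se[keep]
      }
    }
    # reproduce: Bernoulli(rate), parent energy halved, offspring in place
    ns2 <- length(e$sx)
    if (ns2 > 0 && e$srep > 0) {
      born <- which(stats::runif(ns2) < e$srep)
      if (length(born)) {
        e$se[born] <- e$se[born] / 2
        e$sx <- c(e$sx, e$sx[born]); e$sy <- c(e$sy, e$sy[born])
        e$se <- c(e$se, e$se[born])
      }
    }
    if (nw > 0 && e$wrep > 0) {
      born <- which(stats::runif(nw) < e$wrep)
      if (length(born)) {
        e$we[born] <- e$we[born] / 2
        e$wx <- c(e$wx, e$wx[born]); e$wy <- c(e$wy, e$wy[born])
        e$we <- c(e$we, e$we[born])
      }
    }
    # starvation
    keep <- which(e$se > 0)
    e$sx <- e$sx[keep]; e$sy <- e$sy[keep]; e$se <- e$se[keep]
    keep <- which(e$we > 0)
    e$wx <- e$wx[keep]; e$wy <- e$wy[keep]; e$we <- e$we[keep]
    # grass regrowth clock
    idx <- e$countdown > 0L
    e$countdown[idx] <- e$countdown[idx] - 1L
    e$tick <- e$tick + 1L
    out[t, ] <- c(length(e$wx), length(e$sx), sum(e$countdown == 0L))
  }
  data.frame(tick = e$tick - ticks + seq_len(ticks),
             wolves = out[, 1], sheep = out[, 2], grass = out[, 3])
}

#' Lotka-Volterra ODE reference
#'
#' Fixed-step 4th-order Runge-Kutta integration (via \pkg{deSolve}) of the
#' classical system `dx/dt = c1 x - c3 x y`, `dy/dt = c2 y + c4 x y`
#' (`x` prey, `y` predator; `c2` is negative for a decaying predator),
#' the mean-field counterpart of the individual-based model: `c1`/`c2`
#' correspond to the reproduction rates, `c4` to the predator gain from
#' food.
#'
#' @param params Named list/vector with `c1, c2, c3, c4, x0, y0`.
#' @param t_end Final time.
#' @param dt Fixed step size (> 0).
#' @return Data frame with columns `t`, `x`, `y`.
#' @export
lv_reference <- function(params, t_end, dt) {
  stopifnot(dt > 0)
  p <- as.list(params)
  deriv <- function(t, state, parms) {
    x <- state[1]; y <- state[2]
    list(c(p$c1 * x - p$c3 * x * y,
           p$c2 * y + p$c4 * x * y))
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(x = p$x0, y = p$y0), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  data.frame(t = sol[, "time"], x = sol[, "x"], y = sol[, "y"])
}
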