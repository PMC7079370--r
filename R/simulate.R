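#' Square-wave mechanical load
#'
#' Periodic square wave with 50% duty cycle, high phase first: the load
#' equals the magnitude M for \code{(t - phase) mod P < P/2} and the
#' 100 uPa-class baseline otherwise. The phase is fixed at 0 in the default
#' stimulus.
#'
#' @param t time(s) in seconds (vectorised).
#' @param stimulus list with \code{magnitude}, \code{period}, \code{phase},
#'   \code{baseline} (as in \code{cfg$stimulus}).
#' @return numeric vector of loads in micro-Pascal.
#' @examples
#' square_wave(c(0, 600), list(magnitude = 10000, period = 1000,
#'                             phase = 0, baseline = 100))
#' @export
square_wave <- function(t, stimulus) {
  stopifnot(all(t >= 0))
  tm <- (t - stimulus$phase) %% stimulus$period
  ifelse(tm < stimulus$period / 2, stimulus$magnitude, stimulus$baseline)
}

#' Draw reaction timer durations
#'
#' Timer-driven transitions (activation-cycle switches, dissociations) expire
#' after a duration drawn uniformly on a finite support. Exponentially
#' occurring dissociation events conditioned on a bounded observation window
#' are uniform in time, which motivates the uniform law; the mean and support
#' are the experimentally constrained quantities.
#'
#' @param n number of draws.
#' @param mean mean duration in seconds.
#' @param support numeric length-2 \code{c(lo, hi)}; default
#'   \code{c(0, 2*mean)} which preserves the mean.
#' @return numeric vector of \code{n} durations.
#' @export
sample_timer <- function(n, mean, support = c(0, 2 * mean)) {
  stopifnot(mean >= 0, length(support) == 2)
  if (support[2] < support[1]) stop("timer support must satisfy hi >= lo")
  if (mean < support[1] || mean > support[2])
    stop("timer mean must lie inside its support")
  stats::runif(n, support[1], support[2])
}

# internal: translate a sim_config into the flat integer-coded list the
# C++ engine consumes
.engine_conf <- function(cfg, brute_force = FALSE, return_agents = FALSE) {
  sp <- cfg$species
  g <- cfg$geometry
  cls <- match(sp$compartment, .comp_classes) - 1L  # 0 nuc,1 cyt,2 nuc+cyt,3 extra,4 mem
  rmin <- c(0, g$nucleus_radius, 0, g$cell_radius, g$cell_radius)[cls + 1L]
  rmax <- c(g$nucleus_radius, g$cell_radius, g$cell_radius,
            g$extracellular_radius, g$cell_radius)[cls + 1L]
  spid <- function(nm) {
    i <- match(nm, sp$name)
    ifelse(is.na(i), 0L, i) - 1L   # -1 for NA
  }
  br <- cfg$bind_rules
  bind <- cbind(spid(br$a_species), as.integer(br$a_active),
                spid(br$b_species), as.integer(br$b_active),
                as.integer(br$complex), as.integer(br$a_active_after),
                as.integer(br$b_active_after))
  if (!nrow(br)) bind <- matrix(0L, 0, 7)
  ch <- cfg$channels
  sr <- cfg$state_rules
  receptor <- which(cls == 4L & sp$name %in% "integrin")
  if (!length(receptor)) receptor <- which(cls == 4L)
  list(
    n_steps = as.integer(round(cfg$duration / cfg$dt)), dt = cfg$dt,
    sp_count = as.integer(sp$count), sp_init_active = as.integer(sp$init_active),
    sp_comp_class = cls, sp_static = as.integer(sp$static),
    sp_rmin = rmin, sp_rmax = rmax, sp_names = sp$name,
    rn = g$nucleus_radius, rc = g$cell_radius, rx = g$extracellular_radius,
    M = cfg$stimulus$magnitude, P = cfg$stimulus$period,
    phase = cfg$stimulus$phase, m0 = cfg$stimulus$baseline,
    k_act = cfg$k_act, M_ref = cfg$M_ref,
    R_inter = cfg$R_inter, diff_step = cfg$diffusion_step,
    receptor_sp = if (length(receptor)) receptor[1] - 1L else -1L,
    brute_force = isTRUE(brute_force), return_agents = isTRUE(return_agents),
    bind = bind,
    ch_rule = match(ch$bind_rule, br$name) - 1L,
    ch_lo = ch$lo, ch_hi = ch$hi,
    ch_aout = as.integer(ch$a_active_out), ch_bout = as.integer(ch$b_active_out),
    ch_prod = spid(ch$produce),
    ch_stage = as.integer(ch$stage), ch_dissoc = as.integer(ch$dissociate),
    sr_sp = spid(sr$species), sr_act = as.integer(sr$active),
    sr_lo = sr$lo, sr_hi = sr$hi,
    sr_aout = as.integer(sr$active_out), sr_prod = spid(sr$produce),
    sr_gate = ifelse(is.na(sr$gate_compartment), -1L,
                     match(sr$gate_compartment, .comp_names) - 1L),
    sr_die = as.integer(sr$die), sr_become = spid(sr$become)
  )
}

#' Run the stochastic agent-based simulation
#'
#' Executes the discrete-time engine: at each 1 s step the square-wave load
#' sets the integrin activation probability, mobile agents take an isotropic
#' Gaussian Brownian step reflected at their compartment walls, free agents
#' bind the nearest eligible partner within the interaction range (at most
#' one binding per agent per step), internal timers are decremented and
#' expired ones fire their state transitions, dissociations, productions and
#' degradations, and the per-label molecular counts are recorded.
#'
#' Runs are bit-reproducible for a given seed. The returned count matrix has
#' one column per observed state label (see [state_label()]); row sums change
#' only through production and degradation events, which are returned
#' alongside so the integer mass ledger can be audited.
#'
#' @param cfg a \code{"sim_config"}.
#' @param seed integer seed; defaults to the seed stored in \code{cfg}, else 1.
#' @param brute_force use the O(n^2) neighbour scan instead of the spatial
#'   hash (identical results; kept as a correctness oracle).
#' @param return_agents also return the final agent table (positions, states,
#'   timers).
#' @return object of class \code{"state_ts"}: list with \code{times},
#'   \code{counts} (integer matrix, one column per label), \code{labels},
#'   \code{productions}, \code{degradations}, \code{loads}, \code{config},
#'   \code{seed} and optionally \code{agents}.
#' @examples
#' cfg <- default_config(duration = 200)
#' cfg <- apply_scale(cfg, 1 / 40)
#' x <- simulate_cell(cfg, seed = 1)
#' x
#' @export
simulate_cell <- function(cfg, seed = NULL, brute_force = FALSE,
                          return_agents = FALSE) {
  validate_config(cfg)
  seed <- seed %||% cfg$seed %||% 1L
  set.seed(seed)
  res <- .abm_run_cpp(.engine_conf(cfg, brute_force, return_agents))
  counts <- res$counts
  colnames(counts) <- res$labels
  structure(list(
    times = res$times, counts = counts, labels = res$labels,
    productions = res$productions, degradations = res$degradations,
    loads = res$loads, agents = res$agents, config = cfg, seed = seed
  ), class = "state_ts")
}

#' Initial simulation state
#'
#' Convenience wrapper: runs the engine for zero steps and returns the
#' freshly initialised agent table (uniform positions within each label's
#' allowed compartment, membrane receptors on the cell surface shell).
#'
#' @inheritParams simulate_cell
#' @return data.frame of agents.
#' @export
initial_state <- function(cfg, seed = NULL) {
  cfg$duration <- cfg$dt
  cfg$bind_rules <- cfg$bind_rules[0, ]
  cfg$channels <- cfg$channels[0, ]
  cfg$state_rules <- cfg$state_rules[0, ]
  cfg$diffusion_step <- 0
  cfg$stimulus$magnitude <- cfg$stimulus$baseline
  x <- simulate_cell(cfg, seed = seed %||% cfg$seed %||% 1L,
                     return_agents = TRUE)
  x$agents
}

#' Extract a molecular count series
#'
#' Sums the columns of a simulated count matrix matching the given label
#' attributes; e.g. \code{species = "MEK", partner = "RAF"} gives the
#' MEK-bound-RAF complex signal y_i(t) regardless of activation state and
#' compartment.
#'
#' @param x a \code{"state_ts"}.
#' @param species,activation,partner,compartment optional filters; each may
#'   be \code{NULL} (no filter) or a character vector of admitted values.
#' @param label exact label token(s); overrides the attribute filters.
#' @return numeric vector on the time grid of \code{x}.
#' @export
state_series <- function(x, species = NULL, activation = NULL, partner = NULL,
                         compartment = NULL, label = NULL) {
  stopifnot(inherits(x, "state_ts"))
  if (!is.null(label)) {
    miss <- setdiff(label, colnames(x$counts))
    if (length(miss))
      stop("label(s) not present: ", paste(miss, collapse = ", "),
           "; available: ", paste(colnames(x$counts), collapse = ", "))
    keep <- colnames(x$counts) %in% label
  } else {
    p <- parse_label(colnames(x$counts))
    if (!is.null(species) && !any(species %in% p$species))
      stop("species '", paste(species, collapse = ","),
           "' never observed; available labels: ",
           paste(colnames(x$counts), collapse = ", "))
    keep <- rep(TRUE, nrow(p))
    if (!is.null(species)) keep <- keep & p$species %in% species
    if (!is.null(activation)) keep <- keep & p$activation %in% activation
    if (!is.null(partner)) keep <- keep & p$partner %in% partner
    if (!is.null(compartment)) keep <- keep & p$compartment %in% compartment
    # a valid but never-populated state is an all-zero series
    if (!any(keep)) return(numeric(nrow(x$counts)))
  }
  as.numeric(rowSums(x$counts[, keep, drop = FALSE]))
}

#' @export
print.state_ts <- function(x, ...) {
  cat(sprintf("state_ts: %d steps x %d state labels (dt = %g s, seed %s)\n",
              length(x$times) - 1L, ncol(x$counts), x$config$dt,
              format(x$seed)))
  tot <- rowSums(x$counts)
  cat(sprintf("  agents: %d initial, %d final (%d produced, %d degraded)\n",
              tot[1], tot[length(tot)], sum(x$productions),
              sum(x$degradations)))
  top <- sort(colSums(x$counts), decreasing = TRUE)
  cat("  largest pools:",
      paste(names(top)[seq_len(min(4, length(top)))], collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.state_ts <- function(x, labels = NULL, ...) {
  if (is.null(labels)) {
    labels <- names(sort(apply(x$counts, 2, stats::sd),
                         decreasing = TRUE))[seq_len(min(4, ncol(x$counts)))]
  }
  old <- graphics::par(mfrow = c(length(labels), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (lb in labels)
    graphics::plot(x$times, state_series(x, label = lb), type = "l",
                   xlab = "time [s]", ylab = lb, ...)
  invisible(x)
}

#' Write / read a count time series as TSV
#'
#' Plain tab-separated interchange: "#"-prefixed metadata lines, then a
#' header \code{time_s} plus one column per state label token.
#'
#' @param x a \code{"state_ts"}.
#' @param path file path.
#' @return \code{path} (write) or a \code{"state_ts"} with empty provenance
#'   (read), invisibly for write.
#' @export
write_state_ts <- function(x, path) {
  stopifnot(inherits(x, "state_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mechwtd state_ts; seed=%s; dt=%g", format(x$seed),
                     x$config$dt), con)
  df <- data.frame(time_s = x$times, x$counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_ts
#' @export
read_state_ts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("missing time_s column in ", path)
  counts <- as.matrix(df[setdiff(names(df), "time_s")])
  structure(list(times = df$time_s, counts = counts,
                 labels = colnames(counts),
                 productions = NULL, degradations = NULL, loads = NULL,
                 agents = NULL,
                 config = list(dt = if (nrow(df) > 1) diff(df$time_s[1:2])
                               else 1),
                 seed = NA), class = "state_ts")
}
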