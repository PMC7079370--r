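#' Default osteoblast mechanotransduction model configuration
#'
#' Builds the baseline simulation configuration: the species inventory, the
#' reaction network skeleton (integrin -> RAF -> MEK -> ERK -> RUNX2 ->
#' transcription -> translation -> ECM deposition), the nested spherical
#' compartment geometry and the square-wave mechanical stimulus.
#'
#' The network is a documented skeleton of the full osteoblast
#' mechanotransduction diagram: the MAPK activation-cycle timers are exposed
#' by name (see [set_timer()]), while upstream mechanosensing is abstracted to
#' a load-dependent integrin activation probability and downstream gene
#' expression to timed production rules (nuclear active RUNX2 produces mRNA;
#' mRNA plus ribosome produces a vesicle which matures into extracellular
#' ECM protein).
#'
#' The default species counts total 8890 agents. The per-species split is a
#' package default (integrin-heavy membrane pool, balanced MAPK pools):
#' integrin 2000, RAF/MEK/ERK 1200 each, RUNX2 800, ribosome 2000, mRNA 200,
#' ECM protein 290. Every count is configurable.
#'
#' @param magnitude square-wave load magnitude M in micro-Pascal.
#' @param period square-wave period P in seconds.
#' @param duration simulated time in seconds (default 9e4, about 24 h).
#' @param seed optional integer seed recorded in the configuration.
#' @return object of class \code{"sim_config"}.
#' @examples
#' cfg <- default_config(magnitude = 10000, period = 1000, duration = 2000)
#' cfg
#' @export
default_config <- function(magnitude = 10000, period = 1000,
                           duration = 9e4, seed = NULL) {
  species <- data.frame(
    name        = c("integrin", "RAF", "MEK", "ERK", "RUNX2",
                    "ribosome", "mRNA", "vesicle", "ECMprotein"),
    count       = c(2000, 1200, 1200, 1200, 800, 2000, 200, 0, 290),
    init_active = 0,
    compartment = c("membrane", "cytoplasm", "cytoplasm", "cytoplasm",
                    "nucleus+cytoplasm", "cytoplasm", "nucleus+cytoplasm",
                    "cytoplasm", "extracellular"),
    static      = c(TRUE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )

  bind_rules <- data.frame(
    name      = c("integrin_RAF", "RAF_MEK", "MEK_ERK", "ERK_RUNX2",
                  "mRNA_ribosome"),
    a_species = c("integrin", "RAF", "MEK", "ERK", "mRNA"),
    a_active  = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    b_species = c("RAF", "MEK", "ERK", "RUNX2", "ribosome"),
    b_active  = FALSE,
    complex   = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    # activation state of each reactant immediately after the encounter;
    # for a non-complex rule this is an instantaneous messenger transfer
    a_active_after = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    b_active_after = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )

  # stage-0 channels are the printed activation-cycle timers (the bound
  # substrate changes state in place); stage-1 channels are the fast
  # fixed-parameter dissociations that release the activated pair
  channels <- data.frame(
    bind_rule  = c("RAF_MEK", "RAF_MEK",
                   "MEK_ERK", "MEK_ERK", "MEK_ERK",
                   "ERK_RUNX2", "ERK_RUNX2",
                   "mRNA_ribosome"),
    timer_name = c("RAFact+MEKd->MEKact", "RAFMEKact->RAFact+MEKact",
                   "MEKact+ERKd->ERKact", "MEKact+ERKd->MEKact",
                   "MEKERKact->MEKact+ERKact",
                   "ERKact+RUNX2d->ERKact", "ERKRUNX2act->ERKact+RUNX2act",
                   "mRNA+ribosome->vesicle"),
    stage      = c(0, 1, 0, 0, 1, 0, 1, 0),
    mean       = c(90, 10, 90, 90, 10, 90, 10, 300),
    lo         = 0,
    hi         = c(180, 20, 180, 180, 20, 180, 20, 600),
    a_active_out = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    b_active_out = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    dissociate = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    produce    = c(NA, NA, NA, NA, NA, NA, NA, "vesicle"),
    stringsAsFactors = FALSE
  )

  state_rules <- data.frame(
    species    = c("integrin", "RAF", "MEK", "ERK", "RUNX2",
                   "vesicle", "mRNA"),
    active     = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    timer_name = c("integrinact->integrind", "RAFact->RAFd", "MEKact->MEKd",
                   "ERKact->ERKd", "RUNX2act->RUNX2d+mRNA",
                   "vesicle->ECMprotein", "mRNA->0"),
    mean       = c(100, 120, 90, 90, 1320, 600, 10000),
    lo         = 0,
    hi         = c(200, 240, 180, 180, 2640, 1200, 20000),
    active_out = FALSE,
    produce    = c(NA, NA, NA, NA, "mRNA", NA, NA),
    gate_compartment = c(NA, NA, NA, NA, "nucleus", NA, NA),
    die        = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    become     = c(NA, NA, NA, NA, NA, "ECMprotein", NA),
    stringsAsFactors = FALSE
  )

  cfg <- structure(list(
    species     = species,
    bind_rules  = bind_rules,
    channels    = channels,
    state_rules = state_rules,
    stimulus    = list(magnitude = magnitude, period = period,
                       phase = 0, baseline = 100),
    geometry    = list(nucleus_radius = 3, cell_radius = 10,
                       extracellular_radius = 15),
    dt             = 1,
    duration       = duration,
    R_inter        = 1,
    diffusion_step = 0.5,
    k_act          = 0.05,
    M_ref          = 10000,
    scale_factor   = 1,
    seed           = seed
  ), class = "sim_config")
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks structural invariants: non-negative integer counts, positive
#' duration that is a multiple of the time step, nested compartment radii,
#' stimulus magnitude at or above the 100 uPa baseline, rules referencing
#' declared species, and timer means inside their supports. Called internally
#' by every constructor and loader.
#'
#' @param cfg object of class \code{"sim_config"}.
#' @return \code{cfg}, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sp <- cfg$species
  if (any(sp$count < 0) || any(sp$count != round(sp$count)))
    stop("species counts must be non-negative integers")
  if (any(sp$init_active < 0) || any(sp$init_active > sp$count))
    stop("init_active must lie in [0, count] for every species")
  if (!all(sp$compartment %in% .comp_classes))
    stop("unknown compartment class: ",
         paste(setdiff(sp$compartment, .comp_classes), collapse = ", "))
  if (anyDuplicated(sp$name)) stop("duplicated species names")
  if (cfg$dt <= 0) stop("dt must be positive")
  if (cfg$duration <= 0) stop("duration must be positive")
  if (abs(cfg$duration / cfg$dt - round(cfg$duration / cfg$dt)) > 1e-9)
    stop("duration must be a multiple of dt")
  g <- cfg$geometry
  if (!(g$nucleus_radius > 0 && g$nucleus_radius < g$cell_radius &&
        g$cell_radius < g$extracellular_radius))
    stop("compartment radii must satisfy 0 < nucleus < cell < extracellular")
  st <- cfg$stimulus
  if (!(st$baseline > 0 && st$magnitude >= st$baseline))
    stop("stimulus must satisfy M >= baseline > 0")
  if (st$period <= 0) stop("stimulus period must be positive")
  if (cfg$R_inter <= 0) stop("R_inter must be positive")
  if (cfg$diffusion_step < 0) stop("diffusion_step must be non-negative")
  if (cfg$k_act < 0 || cfg$k_act > 1) stop("k_act must lie in [0, 1]")
  if (cfg$M_ref <= st$baseline) stop("M_ref must exceed the load baseline")
  if (cfg$scale_factor <= 0) stop("scale_factor must be positive")

  known <- sp$name
  br <- cfg$bind_rules
  for (i in seq_len(nrow(br))) {
    miss <- setdiff(c(br$a_species[i], br$b_species[i]), known)
    if (length(miss))
      stop("binding rule '", br$name[i], "' references unknown species: ",
           paste(miss, collapse = ", "))
  }
  if (anyDuplicated(br$name)) stop("duplicated binding rule names")
  ch <- cfg$channels
  if (nrow(ch)) {
    bad <- setdiff(ch$bind_rule, br$name[br$complex])
    if (length(bad))
      stop("channel references non-complex or unknown binding rule: ",
           paste(bad, collapse = ", "))
    missp <- setdiff(stats::na.omit(ch$produce), known)
    if (length(missp))
      stop("channel produces unknown species: ", paste(missp, collapse = ", "))
  }
  orphan <- setdiff(br$name[br$complex], ch$bind_rule[ch$stage == 0])
  if (length(orphan))
    stop("complex rule without a stage-0 channel: ",
         paste(orphan, collapse = ", "))
  if (nrow(ch)) {
    if (any(ch$stage < 0 | ch$stage != round(ch$stage)))
      stop("channel stage must be a non-negative integer")
    adv <- ch[!ch$dissociate, , drop = FALSE]
    for (i in seq_len(nrow(adv))) {
      nxt <- ch$bind_rule == adv$bind_rule[i] & ch$stage == adv$stage[i] + 1
      if (!any(nxt))
        stop("non-dissociating channel '", adv$timer_name[i],
             "' has no stage-", adv$stage[i] + 1, " channel to advance to")
    }
  }
  sr <- cfg$state_rules
  if (nrow(sr)) {
    miss <- setdiff(c(sr$species, stats::na.omit(sr$produce),
                      stats::na.omit(sr$become)), known)
    if (length(miss))
      stop("state rule references unknown species: ",
           paste(miss, collapse = ", "))
    gates <- stats::na.omit(sr$gate_compartment)
    if (length(gates) && !all(gates %in% .comp_names))
      stop("unknown gate compartment in state rule")
  }
  for (d in list(ch, sr)) {
    if (nrow(d)) {
      if (any(d$mean < 0) || any(d$lo > d$hi) ||
          any(d$mean < d$lo) || any(d$mean > d$hi))
        stop("timer must satisfy lo <= mean <= hi with mean >= 0")
    }
  }
  invisible(cfg)
}

#' Set a named activation-cycle timer
#'
#' Updates the mean (and support) of a named timer in either the complex
#' dissociation channels or the single-agent state rules. Timer draws are
#' uniform on \code{[lo, hi]}; unless \code{support} is given the support is
#' reset to \code{[0, 2*mean]} so the mean is preserved.
#'
#' @param cfg a \code{"sim_config"}.
#' @param name timer name, e.g. \code{"RAFact+MEKd->MEKact"}.
#' @param mean new mean in seconds.
#' @param support optional numeric length-2 support \code{c(lo, hi)}.
#' @return the updated configuration.
#' @examples
#' cfg <- default_config(duration = 1000)
#' cfg <- set_timer(cfg, "RAFact+MEKd->MEKact", 10)
#' @export
set_timer <- function(cfg, name, mean, support = NULL) {
  stopifnot(inherits(cfg, "sim_config"), mean >= 0)
  if (is.null(support)) support <- c(0, 2 * mean)
  hit <- FALSE
  ic <- cfg$channels$timer_name == name
  if (any(ic)) {
    cfg$channels$mean[ic] <- mean
    cfg$channels$lo[ic] <- support[1]
    cfg$channels$hi[ic] <- support[2]
    hit <- TRUE
  }
  is_ <- cfg$state_rules$timer_name == name
  if (any(is_)) {
    cfg$state_rules$mean[is_] <- mean
    cfg$state_rules$lo[is_] <- support[1]
    cfg$state_rules$hi[is_] <- support[2]
    hit <- TRUE
  }
  if (!hit) stop("no timer named '", name, "'")
  validate_config(cfg)
}

#' Rescale molecular counts and interaction range jointly
#'
#' Multiplies every initial count by \code{s} (rounded half-up) and the
#' interaction range by \code{s^(-1/3)}, so that \code{n * R_inter^3} -- and
#' with it the expected number of potential partners within interaction range
#' of any agent -- is preserved. This keeps the average binding kinetics of
#' the scaled system close to the full-size system, which is what makes
#' desk-scale replicates of cluster-size simulations meaningful.
#'
#' @param cfg a \code{"sim_config"}.
#' @param s positive scale factor (\code{s = 1/8} runs at one eighth the
#'   molecule numbers with \code{R_inter} doubled).
#' @return the rescaled configuration. A warning is emitted if a species used
#'   by some rule rounds to zero count.
#' @examples
#' cfg <- apply_scale(default_config(duration = 1000), 1/8)
#' sum(cfg$species$count)
#' @export
apply_scale <- function(cfg, s) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("scale factor must be a positive number")
  if (s == 1) return(cfg)
  old <- cfg$species$count
  cfg$species$count <- floor(old * s + 0.5)
  cfg$species$init_active <- floor(cfg$species$init_active * s + 0.5)
  cfg$R_inter <- cfg$R_inter * s^(-1 / 3)
  used <- unique(c(cfg$bind_rules$a_species, cfg$bind_rules$b_species,
                   cfg$state_rules$species))
  gone <- cfg$species$name[cfg$species$count == 0 & old > 0 &
                             cfg$species$name %in% used]
  if (length(gone))
    warning("species with active rules scaled to zero count: ",
            paste(gone, collapse = ", "))
  attr(cfg, "applied_scale") <- s * (attr(cfg, "applied_scale") %||% 1)
  validate_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a simulation configuration from YAML or JSON
#'
#' Reads a structured-text configuration and merges it over the documented
#' defaults of [default_config()]: a minimal file naming only a seed yields
#' the full baseline model (8890 agents). Species entries are merged by name;
#' \code{bind_rules}, \code{channels} and \code{state_rules}, when present,
#' replace the default tables wholesale. A \code{scale_factor} field rescales
#' counts and interaction range at load time via [apply_scale()] and is
#' stored back as 1 (counts in the returned object are always literal).
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#'   All times are in seconds, magnitudes in micro-Pascal.
#' @return validated \code{"sim_config"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  cfg <- default_config()
  scalars <- c("dt", "duration", "R_inter", "diffusion_step",
               "k_act", "M_ref", "seed")
  for (f in scalars) if (!is.null(raw[[f]])) cfg[[f]] <- raw[[f]]
  for (f in c("stimulus", "geometry"))
    for (g in names(raw[[f]])) cfg[[f]][[g]] <- raw[[f]][[g]]
  if (!is.null(raw$species)) {
    upd <- .records_to_df(raw$species)
    if (is.null(upd$name)) stop("species entries must be named")
    unknown <- setdiff(upd$name, cfg$species$name)
    if (length(unknown)) {
      add <- cfg$species[rep(1L, length(unknown)), ]
      add$name <- unknown; add$count <- 0; add$init_active <- 0
      add$compartment <- "cytoplasm"; add$static <- FALSE
      cfg$species <- rbind(cfg$species, add)
    }
    i <- match(upd$name, cfg$species$name)
    for (col in setdiff(names(upd), "name"))
      cfg$species[[col]][i[!is.na(upd[[col]])]] <-
        upd[[col]][!is.na(upd[[col]])]
    rownames(cfg$species) <- NULL
  }
  for (f in c("bind_rules", "channels", "state_rules"))
    if (!is.null(raw[[f]]))
      cfg[[f]] <- .records_to_df(raw[[f]], template = cfg[[f]])
  if (!is.null(raw$timers))
    for (nm in names(raw$timers)) cfg <- set_timer(cfg, nm, raw$timers[[nm]])
  validate_config(cfg)
  s <- raw$scale_factor %||% 1
  if (s != 1) cfg <- apply_scale(cfg, s)
  cfg
}

# list-of-records (or record of lists) -> data.frame, with NA for absent
# optional columns taken from a template table
.records_to_df <- function(x, template = NULL) {
  if (is.data.frame(x)) return(x)
  rows <- lapply(x, function(r) {
    r <- lapply(r, function(v) if (is.null(v)) NA else v)
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  cols <- unique(unlist(lapply(rows, names)))
  if (!is.null(template)) cols <- union(cols, names(template))
  rows <- lapply(rows, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  })
  df <- do.call(rbind, rows)
  if (!is.null(template)) {
    for (col in names(template)) {
      if (is.logical(template[[col]]) && !is.logical(df[[col]]))
        df[[col]] <- as.logical(df[[col]])
      if (is.numeric(template[[col]]) && !is.numeric(df[[col]]))
        df[[col]] <- as.numeric(df[[col]])
    }
    df <- df[names(template)]
  }
  df
}

#' Write a simulation configuration to YAML
#'
#' Emits every field of the configuration so that [load_config()] on the
#' written file reconstructs an identical structure (counts are written
#' literally and \code{scale_factor} as 1).
#'
#' @param cfg a \code{"sim_config"}.
#' @param path output file path (\code{.yaml}).
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  df2rec <- function(d) lapply(seq_len(nrow(d)), function(i) {
    r <- as.list(d[i, ])
    r[!vapply(r, function(v) length(v) == 1 && is.na(v), TRUE)]
  })
  out <- list(
    species = df2rec(cfg$species),
    bind_rules = df2rec(cfg$bind_rules),
    channels = df2rec(cfg$channels),
    state_rules = df2rec(cfg$state_rules),
    stimulus = cfg$stimulus, geometry = cfg$geometry,
    dt = cfg$dt, duration = cfg$duration, R_inter = cfg$R_inter,
    diffusion_step = cfg$diffusion_step, k_act = cfg$k_act,
    M_ref = cfg$M_ref, scale_factor = 1
  )
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Osteoblast mechanotransduction simulation configuration\n")
  cat(sprintf("  agents: %d across %d species (+%d initially active)\n",
              sum(x$species$count), nrow(x$species),
              sum(x$species$init_active)))
  cat(sprintf("  stimulus: square wave M = %g uPa, P = %g s, baseline %g uPa\n",
              x$stimulus$magnitude, x$stimulus$period, x$stimulus$baseline))
  cat(sprintf("  duration: %g s at dt = %g s;  R_inter = %.3g, step = %.3g\n",
              x$duration, x$dt, x$R_inter, x$diffusion_step))
  cat(sprintf("  rules: %d binding, %d channels, %d state transitions\n",
              nrow(x$bind_rules), nrow(x$channels), nrow(x$state_rules)))
  invisible(x)
}
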