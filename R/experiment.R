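# Experiment orchestration: conductance titration, the drug study on a
# cohort, the nifedipine concentration-response pipeline and the full
# staged experiment mirroring the workflow used on the rig.

# Quality control mirroring a completed drug run: in every condition the
# simulated I_K1 must engage and a stimulated beat must fire and
# repolarise back below -70 mV.  Cells reported by the workflow are by
# construction cells that completed all conditions.
drug_qc_pass <- function(cell, ik1, cfg,
                         conditions = list(identity,
                                           function(p) apply_drug(p, "bayk8644", 1000),
                                           function(p) apply_drug(p, "nifedipine", 30000))) {
  for (cond in conditions) {
    ccell <- cond(cell)
    eng <- engage_ik1(ccell, ik1, cfg)
    if (!eng$success) return(FALSE)
    stim <- stimulus_train(rate = 0.5, amplitude = 2, count = 1,
                           warn_range = FALSE)
    tr <- run_current_clamp(ccell, ik1, cfg, stim, duration = 2,
                            state0 = eng$state)
    ft <- ap_features(tr, stim_onsets(stim))
    if (!isTRUE(ft$detected[1]) || tail(tr$V_mV, 1) > -70) return(FALSE)
  }
  TRUE
}

#' Nifedipine concentration-inhibition curve from simulated voltage clamp
#'
#' Runs the Ca2+ I-V protocol at each concentration, reads the peak
#' L-type current at the +10 mV step, converts to block fractions
#' relative to the drug-free run and normalises to the maximum observed
#' block.
#'
#' @param cell a [cell_params()] object.
#' @param conc concentrations (nmol/L); default half-log spacing over
#'   10--10000 nmol/L.
#' @return data.frame with columns `conc_nM`, `peak_I_pA`, `block` and
#'   `block_norm`.
#' @export
nifedipine_block_curve <- function(cell, conc = 10^seq(1, 4, by = 0.5)) {
  peak_at_10 <- function(p) {
    pk <- peak_currents(run_voltage_clamp(p, protocol_ca_iv()),
                        current = "I_CaL_pA")
    pk$I[pk$V == 10]
  }
  i0 <- peak_at_10(cell)
  ic <- vapply(conc, function(cc) {
    peak_at_10(apply_drug(cell, "nifedipine", cc))
  }, numeric(1))
  block <- 1 - ic / i0
  data.frame(conc_nM = conc, peak_I_pA = ic, block = block,
             block_norm = block / max(block))
}

#' Titrate the simulated I_K1 conductance on a paced cell
#'
#' Executes a [gk1_titration_schedule()]: level 0 is the constant-current
#' baseline (a holding current found by bisection keeps the diastolic
#' potential at the target); positive levels engage the simulated I_K1
#' with the kick-start manoeuvre and pace without holding current.  All
#' levels use the same stimulus, by default the smallest amplitude that
#' reliably paces the cell at the highest (stiffest) level, so every
#' level of the series is capturable.
#'
#' @param cell a [cell_params()] object.
#' @param schedule a [gk1_titration_schedule()].
#' @param cfg a [clamp_config()].
#' @param ik1_template [ik1_params()] whose density is overridden per
#'   level.
#' @param stim_amplitude stimulus amplitude (nA); `NULL` optimises at
#'   the highest level.
#' @param baseline_V diastolic target (mV) for the level-0 holding
#'   current.
#' @param beats pulses per level; features are taken from the last beat.
#' @return data.frame of class `gk1_titration`: per level the engagement
#'   flag and the action-potential features of the final beat.
#' @export
run_titration <- function(cell, schedule = gk1_titration_schedule(),
                          cfg = clamp_config(),
                          ik1_template = ik1_params(),
                          stim_amplitude = NULL, baseline_V = -94,
                          beats = 3) {
  lvl <- schedule$gk1_density
  with_density <- function(g) { p <- ik1_template; p$gK1_density <- g; p }
  if (is.null(stim_amplitude)) {
    opt <- optimize_stimulus(cell, with_density(max(lvl)), cfg)
    if (!opt$success) stop("no stimulus amplitude paces the cell at the highest level")
    stim_amplitude <- opt$amplitude
  }
  rows <- lapply(seq_along(lvl), function(i) {
    g <- lvl[i]
    if (g == 0) {
      hold <- find_holding_current(cell, baseline_V)
      state0 <- settle_cell(cell, hold, duration = 2,
                            dt = 1 / cfg$tick_rate, substeps = cfg$substeps)
      ik1 <- with_density(0)
      engaged <- TRUE
    } else {
      eng <- engage_ik1(cell, with_density(g), cfg)
      state0 <- eng$state
      ik1 <- with_density(g)
      hold <- 0
      engaged <- eng$success
    }
    if (!engaged) {
      return(data.frame(order = schedule$order[i], gk1_density = g,
                        engaged = FALSE, holding_pA = hold,
                        stim_nA = stim_amplitude, RMP_mV = NA_real_,
                        amplitude_mV = NA_real_, APD90_ms = NA_real_,
                        dVdt_max_V_s = NA_real_, has_plateau = NA))
    }
    stim <- stimulus_train(rate = 0.5, amplitude = stim_amplitude,
                           count = beats, holding_current = hold,
                           warn_range = FALSE)
    tr <- run_current_clamp(cell, ik1, cfg, stim,
                            duration = 0.1 + beats / stim$rate,
                            state0 = state0)
    ft <- ap_features(tr, stim_onsets(stim))
    last <- ft[nrow(ft), ]
    data.frame(order = schedule$order[i], gk1_density = g, engaged = TRUE,
               holding_pA = hold, stim_nA = stim_amplitude,
               RMP_mV = last$RMP_mV, amplitude_mV = last$amplitude_mV,
               APD90_ms = last$APD90_ms, dVdt_max_V_s = last$dVdt_max_V_s,
               has_plateau = last$has_plateau)
  })
  structure(do.call(rbind, rows),
            class = c("gk1_titration", "data.frame"))
}

#' L-type Ca2+ pharmacology on paced hybrid cells
#'
#' Runs control, BayK-8644 (1 umol/L) and nifedipine (30 umol/L)
#' conditions on each cell of a cohort with the simulated I_K1 engaged,
#' and summarises APD90 per condition.  The per-cell stimulus is
#' optimised once under control and reused across conditions.
#'
#' @param cohort list of [cell_params()]; default a generated cohort of
#'   `n` cells that pass the same quality control a rig operator applies
#'   before a drug run (I_K1 engages and a stimulated beat repolarises
#'   back below -70 mV) -- cells failing it are screened out, mirroring
#'   the per-cell success rate of the workflow.
#' @param n,seed cohort size and seed when `cohort` is `NULL`.
#' @param gk1_density simulated I_K1 density (pS/pF) for all conditions.
#' @param bayk_nM,nifedipine_nM drug concentrations (nmol/L).
#' @param cfg a [clamp_config()].
#' @param beats pulses per run; features from the last beat.
#' @return list of class `drug_ap_study`: `per_cell` table, `summary`
#'   (mean, s.e.m., n of APD90 per condition) and `ordering_ok` (BayK >
#'   control > nifedipine in every cell).
#' @export
drug_ap_study <- function(cohort = NULL, n = 6, seed = 1,
                          gk1_density = 267, bayk_nM = 1000,
                          nifedipine_nM = 30000,
                          cfg = clamp_config(), beats = 3) {
  ik1 <- ik1_params(gK1_density = gk1_density)
  if (is.null(cohort)) {
    candidates <- generate_cohort(4 * n, seed, base = make_fixture("B"))
    cohort <- Filter(function(cell) drug_qc_pass(cell, ik1, cfg), candidates)
    if (length(cohort) < n) {
      warning("only ", length(cohort), " of ", n,
              " requested cells passed quality control", call. = FALSE)
    }
    cohort <- cohort[seq_len(min(n, length(cohort)))]
  }
  if (length(cohort) == 0) stop("no cells available for the drug study")
  conds <- function(cell) list(
    control = cell,
    bayk8644 = apply_drug(cell, "bayk8644", bayk_nM),
    nifedipine = apply_drug(cell, "nifedipine", nifedipine_nM))
  rows <- list()
  for (i in seq_along(cohort)) {
    cell <- cohort[[i]]
    opt <- optimize_stimulus(cell, ik1, cfg)
    amp <- if (opt$success) opt$amplitude else 3
    for (cond in names(conds(cell))) {
      ccell <- conds(cell)[[cond]]
      eng <- engage_ik1(ccell, ik1, cfg)
      stim <- stimulus_train(rate = 0.5, amplitude = amp, count = beats,
                             warn_range = FALSE)
      tr <- run_current_clamp(ccell, ik1, cfg, stim,
                              duration = 0.1 + beats / stim$rate,
                              state0 = eng$state)
      ft <- ap_features(tr, stim_onsets(stim))
      last <- ft[nrow(ft), ]
      rows[[length(rows) + 1]] <- data.frame(
        cell = i, condition = cond, engaged = eng$success,
        detected = last$detected, APD90_ms = last$APD90_ms,
        RMP_mV = last$RMP_mV, dVdt_max_V_s = last$dVdt_max_V_s)
    }
  }
  per_cell <- do.call(rbind, rows)
  wide <- stats::reshape(per_cell[, c("cell", "condition", "APD90_ms")],
                         direction = "wide", idvar = "cell",
                         timevar = "condition")
  ordering_ok <- all(wide$APD90_ms.bayk8644 > wide$APD90_ms.control &
                     wide$APD90_ms.control > wide$APD90_ms.nifedipine,
                     na.rm = FALSE)
  summary <- do.call(rbind, lapply(split(per_cell, per_cell$condition),
    function(d) {
      s <- summarize_sem(d$APD90_ms)
      data.frame(condition = d$condition[1], APD90_mean_ms = s$mean,
                 APD90_sem_ms = s$sem, n = s$n)
    }))
  structure(list(per_cell = per_cell, summary = summary,
                 ordering_ok = ordering_ok),
            class = "drug_ap_study")
}

#' @export
print.drug_ap_study <- function(x, ...) {
  cat("Paced L-type Ca2+ pharmacology with simulated I_K1\n")
  print(x$summary, row.names = FALSE)
  cat("APD90 ordering BayK-8644 > control > nifedipine in every cell:",
      x$ordering_ok, "\n")
  invisible(x)
}

#' Run the full staged dynamic-clamp experiment
#'
#' Orchestrates the workflow used per cell on the rig: voltage-clamp
#' quality control (Na+ and Ca2+ I-V families), switch to current clamp,
#' per-cell stimulus optimisation, I_K1 engagement, conductance
#' titration, and an optional drug stage.  Each stage reports a success
#' flag and its artifact; a failed stage aborts the stages that depend
#' on it.  When `plan$cohort` is given, the experiment instead counts
#' per-cell successes across the cohort, optionally with simulated
#' per-cell failures (`plan$failure_prob`, `plan$seed`) standing in for
#' lost seals and capture failures.
#'
#' @param cell a [cell_params()] object.
#' @param plan list: `stages` (default all), `gk1_density` (default
#'   800 pS/pF), `levels` for the titration, `drug` flag, `cohort`,
#'   `failure_prob`, `seed`.
#' @param cfg a [clamp_config()].
#' @return list of class `dc_report`: per-stage results and `success`.
#' @export
run_full_experiment <- function(cell, plan = list(), cfg = clamp_config()) {
  stages <- plan$stages
  if (is.null(stages)) {
    stages <- c("iv_na", "iv_ca", "current_clamp", "stimulus", "engage",
                "titration")
  }
  gk1 <- if (is.null(plan$gk1_density)) 800 else plan$gk1_density
  levels <- if (is.null(plan$levels)) c(0, 200, 400, 800, 1200, 2000) else plan$levels
  report <- list()
  ok <- TRUE

  if (!is.null(plan$cohort)) {
    prob <- if (is.null(plan$failure_prob)) 0 else plan$failure_prob
    seed <- if (is.null(plan$seed)) 1 else plan$seed
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    fail <- stats::runif(length(plan$cohort)) < prob
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    report$cohort <- list(
      n = length(plan$cohort), failed = sum(fail),
      succeeded = sum(!fail),
      success_rate = mean(!fail))
    return(structure(c(report, list(success = TRUE)), class = "dc_report"))
  }

  run_stage <- function(name, expr) {
    if (!ok) return(list(success = FALSE, skipped = TRUE))
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      ok <<- FALSE
      stop("stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    res
  }

  ik1 <- ik1_params(gK1_density = gk1)
  if ("iv_na" %in% stages) {
    report$iv_na <- run_stage("iv_na", {
      sw <- run_voltage_clamp(cell, protocol_na_iv())
      pk <- peak_currents(sw, current = "I_Na_pA")
      list(success = pk$V[which.min(pk$I)] == -30, iv = pk)
    })
  }
  if ("iv_ca" %in% stages) {
    report$iv_ca <- run_stage("iv_ca", {
      sw <- run_voltage_clamp(cell, protocol_ca_iv())
      pk <- peak_currents(sw, current = "I_CaL_pA")
      list(success = pk$V[which.min(pk$I)] == 10, iv = pk)
    })
  }
  if ("current_clamp" %in% stages) {
    report$current_clamp <- run_stage("current_clamp", {
      rest <- settle_cell(cell, 0, duration = 2)$V
      list(success = rest <= 0 & rest >= -15, rest_mV = rest)
    })
  }
  stim_amp <- NULL
  if ("stimulus" %in% stages) {
    report$stimulus <- run_stage("stimulus", {
      opt <- optimize_stimulus(cell, ik1, cfg)
      stim_amp <- opt$amplitude
      c(opt, list(success = opt$success))
    })
    stim_amp <- report$stimulus$amplitude
  }
  if ("engage" %in% stages) {
    report$engage <- run_stage("engage", {
      eng <- engage_ik1(cell, ik1, cfg)
      list(success = eng$success, reason = eng$reason,
           final_V = eng$state$V)
    })
  }
  if ("titration" %in% stages) {
    report$titration <- run_stage("titration", {
      tab <- run_titration(cell, gk1_titration_schedule(levels), cfg,
                           ik1_template = ik1_params(),
                           stim_amplitude = stim_amp)
      list(success = nrow(tab) > 0, table = tab)
    })
  }
  if (isTRUE(plan$drug) || "drug" %in% stages) {
    report$drug <- run_stage("drug", {
      st <- drug_ap_study(cohort = list(cell), gk1_density = gk1, cfg = cfg)
      list(success = st$ordering_ok, study = st)
    })
  }
  stage_ok <- vapply(report, function(s) isTRUE(s$success), logical(1))
  structure(c(report, list(success = all(stage_ok))), class = "dc_report")
}

#' @export
print.dc_report <- function(x, ...) {
  cat("Dynamic-clamp experiment report\n")
  for (nm in setdiff(names(x), "success")) {
    cat(sprintf("  %-14s %s\n", nm,
                if (isTRUE(x[[nm]]$success)) "ok" else "FAILED"))
  }
  cat("overall:", if (isTRUE(x$success)) "ok" else "FAILED", "\n")
  invisible(x)
}
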