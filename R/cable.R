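#' Read a neuronal morphology from an SWC file
#'
#' Parses the standard SWC dialect (columns: id, type, x, y, z, radius in
#' um, parent; `#` comments) into a node table with derived geometry: the
#' frustum membrane area and axial resistance factor of the edge joining
#' each node to its parent. A single-point soma (type 1, no same-type
#' neighbours) is represented as an equivalent sphere of area `4 * pi * r^2`.
#'
#' @param path SWC file path.
#' @return A tibble of class `morphology` with columns `id`, `type`, `x`,
#'   `y`, `z`, `radius_um`, `parent` plus derived `area_cm2` (membrane area
#'   per node) and `edge_len_um`.
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius_um", "parent"))
  as_morphology(tibble::as_tibble(raw))
}

#' @rdname read_swc
#' @param nodes Data frame with the seven SWC columns.
#' @export
as_morphology <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  if (any(nodes$radius_um <= 0)) abort("nonpositive radius in SWC data.")
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1) abort("SWC tree must have exactly one root.")
  idx <- match(nodes$parent, nodes$id)
  orphan <- nodes$parent != -1 & is.na(idx)
  if (any(orphan)) abort("orphan nodes in SWC data (missing parents).")
  # cycle / ordering check: walking to the root must terminate
  depth <- integer(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    j <- i; d <- 0
    while (nodes$parent[j] != -1) {
      j <- idx[j]; d <- d + 1
      if (d > nrow(nodes)) abort("cycle detected in SWC data.")
    }
    depth[i] <- d
  }
  len <- radius_p <- rep(NA_real_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    if (nodes$parent[i] == -1) next
    p <- idx[i]
    len[i] <- sqrt((nodes$x[i] - nodes$x[p])^2 +
                   (nodes$y[i] - nodes$y[p])^2 +
                   (nodes$z[i] - nodes$z[p])^2)
    radius_p[i] <- nodes$radius_um[p]
  }
  # node membrane areas: soma sphere for the root soma node; each child
  # edge is a frustum whose lateral area is split between child and parent
  # (the soma keeps only its sphere).
  area <- rep(0, nrow(nodes))
  soma <- nodes$type == 1
  area[soma] <- 4 * pi * (nodes$radius_um[soma] * 1e-4)^2  # cm^2
  len_eff <- len
  for (i in seq_len(nrow(nodes))) {
    if (nodes$parent[i] == -1) next
    p <- idx[i]
    if (soma[p] && !soma[i]) {
      # neurite stems attach at the soma surface: the stretch of the edge
      # inside the soma sphere carries no membrane and the stem is treated
      # as a cylinder of the child radius
      len_eff[i] <- max(len[i] - nodes$radius_um[p], 0.01)
      r1 <- nodes$radius_um[i] * 1e-4
      r2 <- r1
    } else {
      r1 <- radius_p[i] * 1e-4
      r2 <- nodes$radius_um[i] * 1e-4
    }
    slant <- sqrt((len_eff[i] * 1e-4)^2 + (r1 - r2)^2)
    a_frustum <- pi * (r1 + r2) * slant
    if (soma[p]) {
      area[i] <- area[i] + a_frustum
    } else {
      area[i] <- area[i] + a_frustum / 2
      area[p] <- area[p] + a_frustum / 2
    }
  }
  out <- dplyr::mutate(nodes, area_cm2 = area, edge_len_um = len,
                       edge_len_eff_um = len_eff, depth = depth)
  structure(out, class = c("morphology", class(out)), root = roots)
}

#' Write a morphology as SWC
#' @param morph A `morphology`.
#' @param path Output path.
#' @export
write_swc <- function(morph, path) {
  df <- as.data.frame(morph)[, c("id", "type", "x", "y", "z", "radius_um",
                                 "parent")]
  lines <- c("# SWC written by gabashunt",
             apply(df, 1, function(r)
               paste(format(r, trim = TRUE, scientific = FALSE),
                     collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Refine a morphology by subdividing long edges
#'
#' Splits every edge longer than `max_len_um` into equal sub-segments,
#' interpolating position and radius linearly. Used for spatial-grid
#' convergence checks.
#'
#' @param morph A `morphology`.
#' @param max_len_um Maximum allowed edge length (um).
#' @export
refine_morphology <- function(morph, max_len_um) {
  df <- as.data.frame(morph)[, c("id", "type", "x", "y", "z", "radius_um",
                                 "parent")]
  idx <- match(df$parent, df$id)
  new_rows <- list()
  next_id <- max(df$id) + 1
  for (i in seq_len(nrow(df))) {
    if (df$parent[i] == -1) next
    p <- idx[i]
    L <- sqrt(sum((unlist(df[i, c("x", "y", "z")]) -
                   unlist(df[p, c("x", "y", "z")]))^2))
    k <- ceiling(L / max_len_um)
    if (k <= 1) next
    prev <- df$id[p]
    for (s in seq_len(k - 1)) {
      f <- s / k
      new_rows[[length(new_rows) + 1]] <- data.frame(
        id = next_id, type = df$type[i],
        x = df$x[p] + f * (df$x[i] - df$x[p]),
        y = df$y[p] + f * (df$y[i] - df$y[p]),
        z = df$z[p] + f * (df$z[i] - df$z[p]),
        radius_um = df$radius_um[p] + f * (df$radius_um[i] - df$radius_um[p]),
        parent = prev)
      prev <- next_id
      next_id <- next_id + 1
    }
    df$parent[i] <- prev
  }
  as_morphology(dplyr::bind_rows(df, dplyr::bind_rows(new_rows)))
}

#' Passive membrane parameters
#'
#' Passive constants for the multicompartment control model. The three
#' named conditions carry the per-condition passive reversal (equivalent to
#' RMP) and specific membrane resistance that reproduce the experimentally
#' measured somatic membrane resistances; capacitance, axial resistivity
#' and electrode series resistance are shared.
#'
#' @param condition `"anesthetized"`, `"awake"` or `"nbqx"`.
#' @param c_m_uF_cm2 Specific membrane capacitance (uF/cm^2).
#' @param r_axial_Ohm_cm Axial resistivity (Ohm cm).
#' @param e_pas_mV Passive reversal (mV); default set by condition.
#' @param r_m_Ohm_cm2 Specific membrane resistance (Ohm cm^2); default set
#'   by condition.
#' @param clamp_rs_MOhm Voltage-clamp electrode series resistance (MOhm).
#' @export
passive_params <- function(condition = c("anesthetized", "awake", "nbqx"),
                           c_m_uF_cm2 = 2.515, r_axial_Ohm_cm = 150,
                           e_pas_mV = NULL, r_m_Ohm_cm2 = NULL,
                           clamp_rs_MOhm = 47.5) {
  condition <- match.arg(condition)
  defaults <- list(
    anesthetized = list(e_pas = -70.7, r_m = 10^3.784),
    awake        = list(e_pas = -64.2, r_m = 10^3.540),
    nbqx         = list(e_pas = -71.4, r_m = 10^3.988))
  d <- defaults[[condition]]
  structure(list(condition = condition,
                 c_m_uF_cm2 = c_m_uF_cm2,
                 r_axial_Ohm_cm = r_axial_Ohm_cm,
                 e_pas_mV = e_pas_mV %||% d$e_pas,
                 r_m_Ohm_cm2 = r_m_Ohm_cm2 %||% d$r_m,
                 clamp_rs_MOhm = clamp_rs_MOhm),
            class = "passive_params")
}

# Assemble the passive cable system in units mV / ms / uS / nF / nA.
# Returns per-node membrane conductance g_m (uS), capacitance c (nF) and
# the symmetric axial conductance matrix entries (edge list).
cable_system <- function(morph, params) {
  n <- nrow(morph)
  g_m <- morph$area_cm2 / params$r_m_Ohm_cm2 * 1e6   # S -> uS
  c_n <- params$c_m_uF_cm2 * morph$area_cm2 * 1e3    # uF -> nF
  idx <- match(morph$parent, morph$id)
  e_i <- integer(0); e_j <- integer(0); e_g <- numeric(0)
  for (i in seq_len(n)) {
    if (morph$parent[i] == -1) next
    p <- idx[i]
    r1 <- morph$radius_um[i] * 1e-4
    r2 <- if (morph$type[p] == 1 && morph$type[i] != 1) r1
          else morph$radius_um[p] * 1e-4
    L <- morph$edge_len_eff_um[i] * 1e-4
    # frustum axial resistance: R = rho * L / (pi * r1 * r2)  (Ohm)
    R_Ohm <- params$r_axial_Ohm_cm * L / (pi * r1 * r2)
    e_i <- c(e_i, i); e_j <- c(e_j, p); e_g <- c(e_g, 1e6 / R_Ohm)  # uS
  }
  list(n = n, g_m = g_m, c_n = c_n, edges = list(i = e_i, j = e_j, g = e_g),
       soma = attr(morph, "root"))
}

cable_matrix <- function(sys, extra_diag = numeric(sys$n)) {
  n <- sys$n
  G <- matrix(0, n, n)
  for (k in seq_along(sys$edges$i)) {
    i <- sys$edges$i[k]; j <- sys$edges$j[k]; g <- sys$edges$g[k]
    G[i, j] <- G[i, j] - g
    G[j, i] <- G[j, i] - g
    G[i, i] <- G[i, i] + g
    G[j, j] <- G[j, j] + g
  }
  diag(G) <- diag(G) + sys$g_m + extra_diag
  G
}

#' Place GABA-A synapses near the soma
#'
#' Samples `n_syn` synapse locations uniformly among nodes within
#' `radius_um` of the soma centre. Distance is Euclidean by default; a
#' path-distance alternative is available. Each synapse is an alpha-function
#' conductance `g(t) = g_peak * (t / tau) * exp(1 - t / tau)` (peak
#' `g_peak` at `t = tau`).
#'
#' @param morph A `morphology`.
#' @param n_syn Number of synapses.
#' @param radius_um Inclusion radius around the soma centre (um).
#' @param g_peak_nS Per-synapse peak conductance (nS).
#' @param tau_ms Alpha-function time constant (ms).
#' @param distance `"euclidean"` or `"path"`.
#' @param seed Integer seed.
#' @return A list of class `synapse_placement`: `nodes` (row indices into
#'   the morphology), `g_peak_nS`, `tau_ms`.
#' @export
place_synapses <- function(morph, n_syn = 20, radius_um = 75,
                           g_peak_nS = 2, tau_ms = 150,
                           distance = c("euclidean", "path"), seed = 1) {
  distance <- match.arg(distance)
  soma <- attr(morph, "root")
  if (distance == "euclidean") {
    d <- sqrt((morph$x - morph$x[soma])^2 + (morph$y - morph$y[soma])^2 +
                (morph$z - morph$z[soma])^2)
  } else {
    d <- path_distance_um(morph)
  }
  cand <- which(d <= radius_um)
  if (length(cand) == 0) abort("no morphology nodes within the radius.")
  nodes <- with_seed(seed, sample(cand, n_syn, replace = TRUE))
  structure(list(nodes = nodes, g_peak_nS = g_peak_nS, tau_ms = tau_ms,
                 radius_um = radius_um, distance = distance, seed = seed),
            class = "synapse_placement")
}

path_distance_um <- function(morph) {
  idx <- match(morph$parent, morph$id)
  d <- rep(NA_real_, nrow(morph))
  ord <- order(morph$depth)
  for (i in ord) {
    d[i] <- if (morph$parent[i] == -1) 0 else d[idx[i]] + morph$edge_len_um[i]
  }
  d
}

alpha_conductance <- function(t_ms, g_peak_nS, tau_ms) {
  ifelse(t_ms <= 0, 0,
         g_peak_nS * (t_ms / tau_ms) * exp(1 - t_ms / tau_ms))
}

# Steady-state node voltages under somatic clamp at v_cmd (mV).
cable_steady_state <- function(sys, params, v_cmd, g_syn_nS = NULL,
                               e_gaba = NULL) {
  g_clamp <- 1 / params$clamp_rs_MOhm  # uS
  extra <- numeric(sys$n)
  extra[sys$soma] <- g_clamp
  b <- sys$g_m * params$e_pas_mV
  if (!is.null(g_syn_nS)) {
    extra <- extra + g_syn_nS * 1e-3
    b <- b + g_syn_nS * 1e-3 * e_gaba
  }
  b[sys$soma] <- b[sys$soma] + g_clamp * v_cmd
  A <- cable_matrix(sys, extra)
  as.numeric(solve(A, b))
}

#' Simulate a voltage-clamp ramp experiment on a passive neuron
#'
#' Reproduces, in a passive multicompartment model, the ramp protocol used
#' to estimate the GABA-A reversal potential: an ideal voltage source in
#' series with the electrode resistance clamps the soma, a baseline ramp is
#' applied, then a second ramp during simulated activation of the GABA-A
#' synapses (alpha conductances starting at ramp onset). The cable equation
#' is discretized per SWC node and integrated with an unconditionally
#' stable implicit (backward Euler) scheme. The recorded clamp current is
#' returned as standard VC sweeps so that [fit_iv_ramp()] applies verbatim.
#'
#' @param morph A `morphology`.
#' @param params A [passive_params()].
#' @param placement A [place_synapses()] result (`NULL` for baseline-only).
#' @param e_gaba_mV Reversal potential of the synaptic conductance (mV).
#' @param proto A [protocol()] of kind `"ramp"`.
#' @param dt_ms Time step (ms); default 0.025 (25 us).
#' @param hold_pre_ms Pre-ramp settling time at the holding potential.
#' @param alpha_onset_ms Start of the synaptic alpha conductance, in sweep
#'   time. The default places the conductance *peak* at the midpoint of the
#'   ramp (`hold_pre_ms + ramp/2 - tau`), mirroring the experimental design
#'   in which the evoked GABA-A current is at its peak — and therefore
#'   near-constant — while the ramp is delivered.
#' @return A list with `baseline` and `light` VC sweeps (time in s, command
#'   mV, current pA) and `ramp_window_s`.
#' @export
simulate_clamped_ramp <- function(morph, params, placement, e_gaba_mV,
                                  proto = protocol("ramp"), dt_ms = 0.025,
                                  hold_pre_ms = 100, alpha_onset_ms = NULL) {
  eng <- clamped_ramp_engine(morph, params, placement, proto, dt_ms,
                             hold_pre_ms, alpha_onset_ms)
  list(baseline = eng$run(FALSE, NA_real_),
       light = eng$run(TRUE, e_gaba_mV),
       ramp_window_s = eng$ramp_window_s)
}

# shared stepping engine; run(with_syn, e_gaba) simulates one sweep
clamped_ramp_engine <- function(morph, params, placement, proto, dt_ms,
                                hold_pre_ms, alpha_onset_ms = NULL) {
  if (is.null(alpha_onset_ms) && !is.null(placement))
    alpha_onset_ms <- max(0, hold_pre_ms + proto$ramp_duration_ms / 2 -
                            placement$tau_ms)
  sys <- cable_system(morph, params)
  g_clamp <- 1 / params$clamp_rs_MOhm

  ramp_ms <- proto$ramp_duration_ms
  n_pre <- round(hold_pre_ms / dt_ms)
  n_ramp <- round(ramp_ms / dt_ms)
  t_ms <- seq_len(n_pre + n_ramp) * dt_ms
  v_cmd <- c(rep(proto$ramp_span_mV[1], n_pre),
             proto$ramp_span_mV[1] +
               (seq_len(n_ramp) / n_ramp) * diff(proto$ramp_span_mV))

  extra0 <- numeric(sys$n)
  extra0[sys$soma] <- g_clamp
  inv_dt_c <- sys$c_n / dt_ms
  A0 <- cable_matrix(sys, extra0 + inv_dt_c)
  A0_inv <- solve(A0)
  b0 <- sys$g_m * params$e_pas_mV
  V_init <- cable_steady_state(sys, params, v_cmd[1])

  run <- function(with_syn, e_gaba_mV) {
    V <- V_init
    I_pA <- numeric(length(t_ms))
    syn_nodes <- if (with_syn) placement$nodes else integer(0)
    for (s in seq_along(t_ms)) {
      t_syn <- t_ms[s] - alpha_onset_ms
      b <- b0 + inv_dt_c * V
      b[sys$soma] <- b[sys$soma] + g_clamp * v_cmd[s]
      if (with_syn && t_syn > 0) {
        g_s <- alpha_conductance(t_syn, placement$g_peak_nS,
                                 placement$tau_ms) * 1e-3  # uS
        A <- A0
        for (nd in syn_nodes) {
          A[nd, nd] <- A[nd, nd] + g_s
          b[nd] <- b[nd] + g_s * e_gaba_mV
        }
        V <- as.numeric(solve(A, b))
      } else {
        V <- as.numeric(A0_inv %*% b)
      }
      I_pA[s] <- (v_cmd[s] - V[sys$soma]) * g_clamp * 1e3  # uS*mV=nA -> pA
    }
    sweep_tbl(t_ms / 1e3, v_cmd, I_pA, mode = "VC",
              sweep_id = if (with_syn) "light" else "baseline")
  }
  list(run = run,
       ramp_window_s = c(hold_pre_ms, hold_pre_ms + ramp_ms) / 1e3)
}

#' Somatic input and membrane resistance of the passive model
#'
#' Applies a voltage step (default -10 mV, 500 ms) at the soma through the
#' clamp series resistance, verifies the response has reached steady state,
#' and reports the input resistance `dV / dI` and the membrane resistance
#' `R_input - Rs`.
#'
#' @param morph A `morphology`.
#' @param params A [passive_params()].
#' @param step_mV Step amplitude (mV).
#' @param step_ms Step duration (ms).
#' @param dt_ms Time step for the settling simulation.
#' @param hold_mV Holding potential (mV).
#' @return A one-row tibble: `r_input_MOhm`, `rm_MOhm`, `condition`.
#' @export
somatic_input_resistance <- function(morph, params, step_mV = -10,
                                     step_ms = 500, dt_ms = 0.1,
                                     hold_mV = -70) {
  sys <- cable_system(morph, params)
  g_clamp <- 1 / params$clamp_rs_MOhm
  extra <- numeric(sys$n); extra[sys$soma] <- g_clamp
  inv_dt_c <- sys$c_n / dt_ms
  A_inv <- solve(cable_matrix(sys, extra + inv_dt_c))
  V <- cable_steady_state(sys, params, hold_mV)
  I0 <- (hold_mV - V[sys$soma]) * g_clamp
  v_cmd <- hold_mV + step_mV
  n_steps <- round(step_ms / dt_ms)
  for (s in seq_len(n_steps)) {
    b <- sys$g_m * params$e_pas_mV + inv_dt_c * V
    b[sys$soma] <- b[sys$soma] + g_clamp * v_cmd
    V <- as.numeric(A_inv %*% b)
  }
  I1 <- (v_cmd - V[sys$soma]) * g_clamp
  # steady-state check: one more settling step must not move the current
  b <- sys$g_m * params$e_pas_mV + inv_dt_c * V
  b[sys$soma] <- b[sys$soma] + g_clamp * v_cmd
  V2 <- as.numeric(A_inv %*% b)
  I2 <- (v_cmd - V2[sys$soma]) * g_clamp
  if (abs(I2 - I1) > 1e-6 * abs(I1 - I0))
    abort("voltage step did not reach steady state within the simulated horizon.",
          class = "gabashunt_nonsteady_error")
  r_input <- step_mV / (I1 - I0)  # mV / nA... I in uS*mV = nA -> MOhm
  tibble::tibble(r_input_MOhm = r_input,
                 rm_MOhm = r_input - params$clamp_rs_MOhm,
                 condition = params$condition)
}

#' Series-resistance bias sweep of the reversal-potential estimator
#'
#' For every true synaptic reversal potential on a grid (default -85 to
#' -35 mV in 5 mV increments) the clamped ramp experiment is simulated once
#' and the ramp estimator [fit_iv_ramp()] is applied at each series-
#' resistance correction level (default 0 % and 90 %). The synapse
#' placement is fixed across the sweep.
#'
#' @param morph A `morphology`.
#' @param params A [passive_params()].
#' @param placement A [place_synapses()] result; default placement is
#'   sampled with `seed`.
#' @param egaba_grid_mV True reversal grid (mV).
#' @param corrections Rs correction fractions to analyse.
#' @param proto,dt_ms Passed to [simulate_clamped_ramp()].
#' @param seed Seed for the default placement.
#' @return A tibble of class `bias_curve`: `egaba_true_mV`, `correction`,
#'   `egaba_est_mV`, `bias_mV`, `condition`.
#' @export
run_bias_sweep <- function(morph, params, placement = NULL,
                           egaba_grid_mV = seq(-85, -35, by = 5),
                           corrections = c(0, 0.9),
                           proto = protocol("ramp"), dt_ms = 0.025,
                           seed = 1) {
  if (is.null(placement)) placement <- place_synapses(morph, seed = seed)
  eng <- clamped_ramp_engine(morph, params, placement, proto, dt_ms,
                             hold_pre_ms = 100)
  baseline <- eng$run(FALSE, NA_real_)  # shared across the grid
  rows <- purrr::map_dfr(egaba_grid_mV, function(eg) {
    light <- eng$run(TRUE, eg)
    purrr::map_dfr(corrections, function(fr) {
      fit <- fit_iv_ramp(baseline, light,
                         rs_MOhm = params$clamp_rs_MOhm, rs_fraction = fr,
                         proto = proto, ramp_window_s = eng$ramp_window_s)
      tibble::tibble(egaba_true_mV = eg, correction = fr,
                     egaba_est_mV = fit$egaba_mV,
                     bias_mV = fit$egaba_mV - eg)
    })
  })
  rows$condition <- params$condition
  structure(rows, class = c("bias_curve", class(rows)))
}
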