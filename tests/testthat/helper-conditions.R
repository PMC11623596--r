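# Canonical generating conditions shared across the suite.
#
# The dark state is parameterized to turn over at ~0.6/s at 25 C with an
# activation enthalpy of 14 kcal/mol; the lit state is shifted by the
# allosteric energetics under study (ddH = -1665 cal/mol and an entropic
# term of T*ddS = -1536 cal/mol at 30 C), so every recovery test knows its
# ground truth exactly.

R_cal_h <- 1.987
kb_over_h_h <- 1.380649e-23 / 6.62607015e-34

# entropy that yields a given kcat at 25 C for a given activation enthalpy
dS_for_kcat25 <- function(kcat25, dH_act) {
  T_K <- 298.15
  R_cal_h * (log(kcat25 / (kb_over_h_h * T_K)) + dH_act / (R_cal_h * T_K))
}

dark_truth <- function(cv = 0.05, seed = 1L) {
  true_params(dH_act = 14000, dS_act = dS_for_kcat25(0.6, 14000),
              kcat_cv = cv, seed = seed)
}

# lit state displaced by (ddH, T*ddS at T_ref) from the dark state
lit_truth <- function(ddH = -1665, TddS = -1536, T_ref = 303.15,
                      cv = 0.05, seed = 2L) {
  dp <- dark_truth(cv)
  true_params(dH_act = dp$dH_act + ddH,
              dS_act = dp$dS_act + TddS / T_ref,
              kcat_cv = cv, seed = seed)
}

# lit state constructed to give an exact kcat ratio at a temperature
lit_truth_for_ratio <- function(ratio, at_K = 298.15, ddH = -1665,
                                cv = 0.05, seed = 2L) {
  dp <- dark_truth(cv)
  ddG <- -R_cal_h * at_K * log(ratio)
  dds <- (ddH - ddG) / at_K
  true_params(dH_act = dp$dH_act + ddH, dS_act = dp$dS_act + dds,
              kcat_cv = cv, seed = seed)
}

# a raw kinetic_trace from plain vectors (bypasses the generator, for
# arithmetic tests on hand-written traces)
manual_trace <- function(time_s, absorbance, enzyme_conc_M = 1e-7,
                         epsilon_mM_cm = 13.2, pathlength_cm = 1,
                         temp_C = 25, condition = "dark") {
  litdark:::new_kinetic_trace(
    tibble::tibble(time_s = time_s, absorbance = absorbance),
    temp_C = temp_C, condition = condition, enzyme_conc_M = enzyme_conc_M,
    epsilon_mM_cm = epsilon_mM_cm, pathlength_cm = pathlength_cm,
    wavelength_nm = 340
  )
}

# independent brute-force Eyring oracle: coarse-to-fine grid search
# minimizing the SSE of ln(kcat) against the transition-state rate law,
# written without touching the package's fitting path
eyring_grid_oracle <- function(temp_C, kcat, dH_range = c(5000, 25000),
                               dS_range = c(-40, 10)) {
  T_K <- temp_C + 273.15
  y <- log(kcat)
  sse <- function(dH, dS) {
    mu <- log(kb_over_h_h * T_K) - dH / (R_cal_h * T_K) + dS / R_cal_h
    sum((y - mu)^2)
  }
  step_H <- 250; step_S <- 1
  repeat {
    dHs <- seq(dH_range[1], dH_range[2], by = step_H)
    dSs <- seq(dS_range[1], dS_range[2], by = step_S)
    grid <- expand.grid(dH = dHs, dS = dSs)
    vals <- mapply(sse, grid$dH, grid$dS)
    best <- grid[which.min(vals), ]
    if (step_H <= 0.1) break
    # generous window: (dH, dS) are strongly correlated along a ridge
    dH_range <- best$dH + c(-4, 4) * step_H
    dS_range <- best$dS + c(-4, 4) * step_S
    step_H <- step_H / 5
    step_S <- step_S / 5
  }
  list(dH_act = best$dH, dS_act = best$dS)
}
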