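#' Assemble a per-variant record from kinetic and melt results
#'
#' Joins the lit/dark bootstrap Eyring fits and the lit/dark melt fits of
#' one construct into a single record: allosteric energetics (via
#' [allostery_energetics()]), melting temperatures and their lit-minus-dark
#' difference, and the fold change at the reference temperature with its
#' bootstrap CI. Missing or flagged inputs yield an incomplete record with
#' the absent fields listed in `missing`, not an error.
#'
#' @param lit_fit,dark_fit `eyring_fit` objects with bootstrap
#'   distributions (see [bootstrap_eyring()]); `NULL` if unavailable.
#' @param lit_melt,dark_melt `melt_fit` objects (see [fit_two_state()]);
#'   `NULL` if unavailable.
#' @param T_ref Reference temperature in kelvin.
#' @param variant Construct label.
#' @return An object of class `variant_record`.
#' @export
build_variant_record <- function(lit_fit, dark_fit, lit_melt, dark_melt,
                                 T_ref = 303.15, variant = "DL121") {
  missing <- character(0)
  energetics <- NULL
  if (is.null(lit_fit) || is.null(dark_fit)) {
    missing <- c(missing, "energetics")
  } else {
    energetics <- allostery_energetics(lit_fit, dark_fit, T_ref = T_ref)
  }
  melt_ok <- function(m) !is.null(m) && isTRUE(m$accepted)
  Tm_lit <- if (melt_ok(lit_melt)) lit_melt$Tm else NA_real_
  Tm_dark <- if (melt_ok(dark_melt)) dark_melt$Tm else NA_real_
  if (is.na(Tm_lit)) missing <- c(missing, "Tm_lit")
  if (is.na(Tm_dark)) missing <- c(missing, "Tm_dark")

  fold_ci <- c(NA_real_, NA_real_)
  fold <- NA_real_
  if (!is.null(energetics)) {
    fold <- energetics$fold_change_at_ref
    row <- energetics$ci[energetics$ci$quantity == "fold_change_at_ref", ]
    fold_ci <- c(row$lower, row$upper)
  }
  structure(
    list(variant = variant, energetics = energetics,
         Tm_lit = Tm_lit, Tm_dark = Tm_dark, dTm = Tm_lit - Tm_dark,
         fold_change_at_ref = fold, fold_ci = fold_ci, T_ref = T_ref,
         classification = NA_character_, missing = missing),
    class = "variant_record"
  )
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("Variant %s (T_ref = %.2f K)\n", x$variant, x$T_ref))
  if (length(x$missing)) {
    cat("  missing fields:", paste(x$missing, collapse = ", "), "\n")
  }
  if (!is.null(x$energetics)) {
    cat(sprintf("  ddG = %.0f cal/mol, fold change = %.3f [%.3f, %.3f]\n",
                x$energetics$ddG_at_ref, x$fold_change_at_ref,
                x$fold_ci[1], x$fold_ci[2]))
  }
  cat(sprintf("  Tm lit/dark = %.2f / %.2f C (dTm = %.2f)\n",
              x$Tm_lit, x$Tm_dark, x$dTm))
  if (!is.na(x$classification)) {
    cat("  classification:", x$classification, "\n")
  }
  invisible(x)
}

#' Classify a variant's allosteric effect against a reference construct
#'
#' Compares 95% bootstrap confidence intervals of the fold change at the
#' reference temperature: a variant whose CI lies entirely above the
#' reference's CI is `"enhancing"`, entirely below is `"disrupting"`, and
#' any overlap is `"neutral"`. A record compared against itself (or any
#' record with an identical interval) is therefore always neutral.
#'
#' @param record,reference `variant_record` objects with energetics.
#' @return One of `"enhancing"`, `"disrupting"`, `"neutral"`.
#' @export
classify_variant <- function(record, reference) {
  stopifnot(inherits(record, "variant_record"),
            inherits(reference, "variant_record"))
  if (anyNA(record$fold_ci) || anyNA(reference$fold_ci)) {
    return(NA_character_)
  }
  if (record$fold_ci[1] > reference$fold_ci[2]) {
    "enhancing"
  } else if (record$fold_ci[2] < reference$fold_ci[1]) {
    "disrupting"
  } else {
    "neutral"
  }
}

#' Flatten variant records into a panel tibble
#'
#' @param records A list of `variant_record` objects.
#' @param reference_variant Label of the construct used to classify the
#'   others (itself classified neutral); `NULL` skips classification.
#' @return A tibble with one row per variant: `variant`, `ddH`, `ddS`,
#'   `TddS`, `ddG`, `fold`, `fold_lo`, `fold_hi`, `Tm_lit`, `Tm_dark`,
#'   `dTm`, `classification`.
#' @export
variant_panel <- function(records, reference_variant = "DL121") {
  stopifnot(all(vapply(records, inherits, logical(1), "variant_record")))
  if (!is.null(reference_variant)) {
    labels <- vapply(records, `[[`, character(1), "variant")
    iref <- match(reference_variant, labels)
    if (!is.na(iref)) {
      records <- lapply(records, function(r) {
        r$classification <- classify_variant(r, records[[iref]])
        r
      })
    }
  }
  purrr::map_dfr(records, function(r) {
    e <- r$energetics
    tibble::tibble(
      variant = r$variant,
      ddH = if (is.null(e)) NA_real_ else e$ddH,
      ddS = if (is.null(e)) NA_real_ else e$ddS,
      TddS = if (is.null(e)) NA_real_ else e$TddS_at_ref,
      ddG = if (is.null(e)) NA_real_ else e$ddG_at_ref,
      fold = r$fold_change_at_ref,
      fold_lo = r$fold_ci[1], fold_hi = r$fold_ci[2],
      Tm_lit = r$Tm_lit, Tm_dark = r$Tm_dark, dTm = r$dTm,
      classification = r$classification
    )
  })
}

#' Enthalpy-entropy tradeoff coordinates
#'
#' Places each variant at `x = T_ref * ddS`, `y = ddH` (both cal/mol). On
#' the `x = y` diagonal the entropic and enthalpic effects of light cancel
#' exactly and the allosteric free-energy change is zero; the signed
#' off-diagonal offset `gain = x - y = -ddG` (cal/mol) is the net
#' allosteric free-energy gain. The offset is invariant to translating a
#' point along the diagonal. Bootstrap CIs for the gain are attached when
#' the records carry energetics.
#'
#' @param records A list of `variant_record` objects, or a
#'   [variant_panel()] tibble (point coordinates only in that case).
#' @param T_ref Reference temperature (K); defaults to the records' own.
#' @return A tibble: `variant`, `x_TddS`, `y_ddH`, `gain`, `gain_lo`,
#'   `gain_hi`.
#' @export
tradeoff_coordinates <- function(records, T_ref = NULL) {
  if (is.data.frame(records)) {
    df <- records
    if (!all(c("TddS", "ddH") %in% names(df))) {
      abort("Panel must contain `TddS` and `ddH` columns.",
            class = "litdark_bad_params")
    }
    return(tibble::tibble(variant = df$variant, x_TddS = df$TddS,
                          y_ddH = df$ddH, gain = df$TddS - df$ddH,
                          gain_lo = NA_real_, gain_hi = NA_real_))
  }
  stopifnot(all(vapply(records, inherits, logical(1), "variant_record")))
  purrr::map_dfr(records, function(r) {
    e <- r$energetics
    if (is.null(e)) {
      abort(sprintf("Variant %s has no energetics.", r$variant),
            class = "litdark_bad_params")
    }
    Tr <- T_ref %||% e$T_ref
    x <- Tr * e$ddS
    y <- e$ddH
    gain_boot <- Tr * e$boot$ddS - e$boot$ddH
    qs <- quantile(gain_boot, c(0.025, 0.975))
    tibble::tibble(variant = r$variant, x_TddS = x, y_ddH = y,
                   gain = x - y, gain_lo = unname(qs[1]),
                   gain_hi = unname(qs[2]))
  })
}

#' Temperature profile of the allosteric fold change
#'
#' Evaluates [predicted_fold_change()] over a temperature range for one
#' record. Profiles are monotone decreasing when `ddH < 0` and steeper the
#' more negative `ddH` is; two variants with equal `ddG` at some
#' temperature cross there.
#'
#' @param record A `variant_record` (or `allostery_energetics`) object.
#' @param temps_K Temperatures (K) to evaluate.
#' @return A tibble: `variant`, `temp_K`, `temp_C`, `fold`, `lower`,
#'   `upper`.
#' @export
temperature_profile <- function(record,
                                temps_K = seq(278.15, 313.15, by = 1)) {
  e <- if (inherits(record, "variant_record")) record$energetics else record
  if (!inherits(e, "allostery_energetics")) {
    abort("Energetics are required.", class = "litdark_bad_params")
  }
  label <- if (inherits(record, "variant_record")) record$variant else NA_character_
  prof <- predicted_fold_change(e, temps_K, with_ci = TRUE)
  dplyr::mutate(prof, variant = label,
                temp_C = kelvin_to_celsius(.data$temp_K),
                .before = 1)
}

#' Stability-activity correlation across a variant panel
#'
#' Ordinary least-squares line of best fit of the lit-minus-dark melting
#' temperature change (`dTm`, degrees C) on the allosteric transition-state
#' free energy change (`ddG`, cal/mol), plus the Pearson correlation. The
#' exclusion set is an explicit argument (some variants alter lit/dark
#' stability without a matching allosteric effect and are omitted from the
#' printed line); both regression directions are reported since the choice
#' of regressor is a presentation decision.
#'
#' @param panel A [variant_panel()] tibble with columns `variant`, `ddG`,
#'   `dTm`.
#' @param exclude Character vector of variant labels to omit; every label
#'   must be present in the panel.
#' @return An object of class `correlation_result`: `slope`, `intercept`
#'   (dTm on ddG), `reverse_slope`, `reverse_intercept` (ddG on dTm),
#'   `pearson_r`, `n_used`, `excluded`, and the data used.
#' @export
stability_activity_correlation <- function(panel, exclude = character(0)) {
  req <- c("variant", "ddG", "dTm")
  if (!all(req %in% names(panel))) {
    abort("Panel needs columns `variant`, `ddG`, `dTm`.",
          class = "litdark_bad_params")
  }
  unknown <- setdiff(exclude, panel$variant)
  if (length(unknown)) {
    abort(sprintf("Excluded variant(s) not in the panel: %s",
                  paste(unknown, collapse = ", ")),
          class = "litdark_bad_params")
  }
  used <- dplyr::filter(panel, !.data$variant %in% exclude)
  used <- dplyr::filter(used, !is.na(.data$ddG), !is.na(.data$dTm))
  if (nrow(used) < 3) {
    abort("Need >= 3 records after exclusion.",
          class = "litdark_too_few_points")
  }
  fwd <- coef(lm(dTm ~ ddG, data = used))
  rev <- coef(lm(ddG ~ dTm, data = used))
  structure(
    list(slope = unname(fwd[2]), intercept = unname(fwd[1]),
         reverse_slope = unname(rev[2]), reverse_intercept = unname(rev[1]),
         pearson_r = cor(used$ddG, used$dTm),
         n_used = nrow(used), excluded = sort(exclude), data = used),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Stability-activity correlation\n")
  cat(sprintf("  dTm = %.4g + %.4g * ddG  (n = %d, Pearson r = %.3f)\n",
              x$intercept, x$slope, x$n_used, x$pearson_r))
  if (length(x$excluded)) {
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
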