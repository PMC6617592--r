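#' Example cultivar trait summary
#'
#' Per-cultivar trait means from a field trial of 12 perennial ryegrass
#' cultivars (three replicate single-row plots each) scanned recurrently
#' with a ground-based LiDAR platform and then mechanically harvested:
#' fresh weight (`fw_g`, g/row), dry weight (`dw_g`, g/row), the printed
#' dry-matter fraction (`pdm_printed`, 2 dp), the LiDAR Volume index
#' (`lv`) and ploidy. Useful as a worked example for
#' [coefficient_of_variation()], [percent_dm()] and
#' [normalized_covariance()].
#'
#' @return A 12-row tibble.
#' @examples
#' coefficient_of_variation(ryegrass_cultivar_traits()$fw_g)
#' @export
ryegrass_cultivar_traits <- function() {
  tibble(
    cultivar = 1:12,
    fw_g = c(525.00, 655.00, 391.42, 579.75, 498.39, 403.11,
             370.61, 499.67, 514.49, 522.54, 475.96, 317.75),
    dw_g = c(154.15, 190.14, 130.49, 188.97, 141.70, 131.24,
             126.08, 147.76, 171.25, 158.45, 161.89, 108.53),
    pdm_printed = c(0.29, 0.29, 0.33, 0.33, 0.28, 0.33,
                    0.34, 0.30, 0.33, 0.30, 0.34, 0.34),
    lv = c(16841584, 24446478, 17199440, 18919565, 22324398, 17012703,
           14231352, 19571709, 20948934, 19316282, 20783519, 15633334),
    ploidy = c("2x", "4x", "4x", "2x", "2x", "4x",
               "2x", "2x", "2x", "4x", "2x", "2x"))
}

#' Example cultivar regression parameters
#'
#' Published per-cultivar calibration parameters for the same 12-cultivar
#' trial: the LiDAR Volume index regressed on fresh weight for each
#' cultivar over three scan dates. Columns: mean `slope` and its SD,
#' mean `y_intercept` and its SD, the printed `x_intercept`
#' (`-y_intercept / slope`, in grams: the fresh weight at which the index
#' extrapolates to zero), `r2`, and the p-value of the slope. `r2` is `NA`
#' where it was not printed.
#'
#' @return A 12-row tibble.
#' @examples
#' p <- ryegrass_cultivar_regressions()
#' all.equal(p$x_intercept, round(-p$y_intercept / p$slope, 2),
#'           tolerance = 0.01)
#' @export
ryegrass_cultivar_regressions <- function() {
  tibble(
    cultivar = 1:12,
    slope = c(251687, 367976, 268352, 296257, 375228, 254370,
              213756, 287494, 288594, 318106, 333438, 212148),
    slope_sd = c(18797, 9248, 31270, 50781, 14687, 8264,
                 2424, 957.5, 2449, 5578, 16568, 7899),
    y_intercept = c(-24786555, -36712222, -27599719, -29848658, -39844763,
                    -25279526, -21271669, -28144506, -26977390, -33444196,
                    -34701094, -19647030),
    y_intercept_sd = c(2701665, 1329168, 4494494, 7298879, 2111043,
                       1187740, 348411, 137617, 351961, 801692,
                       2381281, 1135327),
    x_intercept = c(98.48, 99.77, 102.8, 100.8, 106.2, 99.38,
                    99.51, 97.91, 93.48, 105.1, 104.1, 92.61),
    r2 = c(0.9945, 0.9994, 0.9866, 0.9715, 0.9985, 0.9989,
           0.9999, NA, 0.9999, 0.9997, 0.9975, 0.9986),
    p_slope = c(0.0475, 0.016, 0.0739, 0.1081, 0.0249, 0.0207,
                0.0072, 0.0021, 0.0054, 0.0112, 0.0316, 0.0237))
}
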