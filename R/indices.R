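#' Differential average (DAve) index
#'
#' DAve compares the averaged spectral counts (aSpC) of a protein in two
#' samples X and Y as \deqn{DAve = \frac{X - Y}{(X + Y) \cdot 0.5} =
#' \frac{2(X - Y)}{X + Y},} a bounded, fold-change-like index ranging from
#' +2.00 (detected only in X) to -2.00 (detected only in Y). A value of 0
#' means equal averaged counts; |DAve| >= 0.4 is algebraically equivalent to
#' a fold change >= 1.5 for strictly positive pairs.
#'
#' @param x,y non-negative averaged spectral counts (vectorized).
#' @return Numeric vector of DAve values in \[-2, 2\]; `NA` where
#'   `x + y == 0` (the pair is not comparable — DAve is 0/0 there).
#' @examples
#' dave(3, 2)   # 0.4, the significance threshold (fold change 1.5)
#' dave(5, 0)   # 2, the maximum
#' @export
dave <- function(x, y) {
  stopifnot(all(x >= 0, na.rm = TRUE), all(y >= 0, na.rm = TRUE))
  out <- 2 * (x - y) / (x + y)
  out[(x + y) == 0] <- NA_real_
  out
}

#' Differential confidence index (DCI)
#'
#' DCI weights the spectral-count difference by total abundance,
#' \deqn{DCI = (X + Y) \cdot \frac{X - Y}{2},} so that a given relative
#' change scores higher confidence when supported by more spectra. Its sign
#' always matches DAve's; it is unbounded and scales quadratically when both
#' counts are scaled by a common factor.
#'
#' @inheritParams dave
#' @return Numeric vector of DCI values (0 where `x + y == 0`).
#' @examples
#' dci(3, 2)    # 2.5
#' dci(10, 5)   # 37.5
#' @export
dci <- function(x, y) {
  stopifnot(all(x >= 0, na.rm = TRUE), all(y >= 0, na.rm = TRUE))
  (x + y) * (x - y) / 2
}

#' Significance thresholds for the DAve/DCI filter
#'
#' @param t_dave positive DAve threshold (default 0.4, i.e. fold change 1.5).
#' @param t_dci positive DCI threshold (default 5).
#' @return A list of class `spc_thresholds`.
#' @export
spc_thresholds <- function(t_dave = 0.4, t_dci = 5) {
  stopifnot(is.numeric(t_dave), is.numeric(t_dci),
            t_dave > 0, t_dci > 0)
  structure(list(t_dave = t_dave, t_dci = t_dci), class = "spc_thresholds")
}

#' Classify a protein's differential status from DAve and DCI
#'
#' A protein is called up-represented in the first sample (X) when
#' DAve >= +t_dave AND DCI >= +t_dci, up-represented in the second sample
#' (Y) when DAve <= -t_dave AND DCI <= -t_dci, and not significant
#' otherwise. Boundaries are inclusive. A pair with no numeric DAve
#' (x = y = 0) is not comparable.
#'
#' @param dave_value,dci_value numeric vectors (DAve may be `NA` for
#'   not-comparable pairs).
#' @param th an [spc_thresholds()] object.
#' @return Character vector with values `"up_in_X"`, `"up_in_Y"`,
#'   `"not_significant"`, `"not_comparable"`.
#' @export
classify <- function(dave_value, dci_value, th = spc_thresholds()) {
  stopifnot(inherits(th, "spc_thresholds"),
            length(dave_value) == length(dci_value))
  out <- rep("not_significant", length(dave_value))
  out[!is.na(dave_value) &
        dave_value >= th$t_dave & dci_value >= th$t_dci] <- "up_in_X"
  out[!is.na(dave_value) &
        dave_value <= -th$t_dave & dci_value <= -th$t_dci] <- "up_in_Y"
  out[is.na(dave_value)] <- "not_comparable"
  out
}

#' DAve value equivalent to a given fold change
#'
#' Maps a fold change r >= 1 to the DAve score of any pair with x/y = r:
#' DAve = 2(r - 1)/(r + 1). The default significance threshold 0.4
#' corresponds exactly to a 1.5-fold change; DAve tends to 2 as r grows.
#'
#' @param r fold change, >= 1 (invert the ratio for down-changes).
#' @return DAve value in \[0, 2).
#' @examples
#' fold_change_equivalent(1.5)  # 0.4
#' fold_change_equivalent(3)    # 1
#' @export
fold_change_equivalent <- function(r) {
  if (any(r < 1)) {
    stop("r must be >= 1; invert the ratio for fold changes below 1",
         call. = FALSE)
  }
  2 * (r - 1) / (r + 1)
}

# discrete color ramps, one shade per intensity level (light, then 1..4
# quarters of [t_dave, 2] by |DAve|)
.red_ramp <- c(light = "#F9CFCC", "#F1948A", "#E74C3C", "#C0392B",
               "#922B21")
.blue_ramp <- c(light = "#CCDFF9", "#85C1E9", "#3498DB", "#2874A6",
                "#1B4F72")

#' Color code for a DAve value
#'
#' Reproduces the chromatic scale of the differential table: red hues for
#' positive DAve (up in the first sample), blue for negative, white for 0 or
#' a not-comparable pair. Intensity |DAve|/2 is mapped to a discrete
#' four-step ramp over \[t_dave, 2\] (quarter-width bins, upper bound
#' inclusive); pairs below the DAve threshold, or failing the joint
#' significance filter (e.g. on DCI), get the light shade of their hue.
#'
#' @param dave_value numeric vector of DAve values in \[-2, 2\], `NA`
#'   allowed for not-comparable pairs.
#' @param significant logical vector: did the protein pass the joint
#'   DAve/DCI filter in this comparison?
#' @param t_dave DAve threshold separating light from graded shades.
#' @return data.frame with columns `hue` ("red"/"blue"/"white"), `level`
#'   (0 = white, 1..4 = graded ramp, NA = light), `light` (logical) and
#'   `hex` (display color).
#' @export
color_for <- function(dave_value, significant = TRUE, t_dave = 0.4) {
  n <- length(dave_value)
  significant <- rep_len(significant, n)
  if (any(abs(dave_value) > 2 + 1e-9, na.rm = TRUE)) {
    stop("DAve values must lie in [-2, 2]", call. = FALSE)
  }
  hue <- ifelse(is.na(dave_value) | dave_value == 0, "white",
                ifelse(dave_value > 0, "red", "blue"))
  light <- !is.na(dave_value) & dave_value != 0 &
    (abs(dave_value) < t_dave | !significant)
  width <- (2 - t_dave) / 4
  level <- as.integer(pmin(pmax(ceiling((abs(dave_value) - t_dave) / width),
                                1), 4))
  level[hue == "white"] <- 0L
  level[light] <- NA_integer_
  hex <- rep("#FFFFFF", n)
  for (i in seq_len(n)) {
    if (hue[i] == "white") next
    ramp <- if (hue[i] == "red") .red_ramp else .blue_ramp
    hex[i] <- if (light[i]) ramp[["light"]] else ramp[[level[i] + 1L]]
  }
  data.frame(hue = hue, level = level, light = light, hex = hex,
             stringsAsFactors = FALSE)
}

#' Format a share of proteins as a printed percentage
#'
#' Percentages are rounded to one decimal place and trailing ".0" is
#' dropped, so 48/447 prints as "10.7%" and 18/447 as "4%".
#'
#' @param count numerator (vectorized).
#' @param total denominator.
#' @return Character vector like `"10.7%"`.
#' @export
format_percent <- function(count, total) {
  p <- round(100 * count / total, 1)
  s <- formatC(p, format = "f", digits = 1)
  s <- sub("\\.0$", "", s)
  paste0(s, "%")
}
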