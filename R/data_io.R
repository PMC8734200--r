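#' Assemble a validated two-drug dose-response data set
#'
#' A dose-response data set is a tibble with one row per well: the doses of
#' the two compounds and the measured response. Replicated dose pairs are
#' kept as separate rows. Metadata (drug names, dose unit, response scale,
#' effect direction) travel as attributes so that the object still behaves
#' as an ordinary tibble in dplyr pipelines.
#'
#' @param data A data frame with numeric columns `dose1`, `dose2`, `response`.
#' @param drug1,drug2 Compound names (used in plots and reports).
#' @param dose_unit Unit of the dose axes, e.g. `"uM"`.
#' @param response_scale `"percent"` for 0-100 data, `"fraction"` for 0-1 data.
#' @param direction `"inhibitory"` (response decreases with dose, the default
#'   throughout) or `"stimulatory"`.
#'
#' @return A tibble of class `dose_response` with columns
#'   `dose1`, `dose2`, `response`.
#'
#' @details Validation enforces the design assumptions used downstream:
#' non-negative finite doses, finite responses, and the presence of
#' monotherapy rows (`dose1 == 0` and `dose2 == 0` must each occur) --
#' without monotherapy data no null reference can be built.
#'
#' @examples
#' d <- dose_response(data.frame(
#'   dose1 = c(0, 0, 1, 1), dose2 = c(0, 1, 0, 1),
#'   response = c(100, 70, 80, 40)
#' ))
#' d
#' @export
dose_response <- function(data,
                          drug1 = "drug1", drug2 = "drug2",
                          dose_unit = "conc",
                          response_scale = c("percent", "fraction"),
                          direction = c("inhibitory", "stimulatory")) {
  response_scale <- match.arg(response_scale)
  direction <- match.arg(direction)
  need <- c("dose1", "dose2", "response")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)[need]
  for (col in need) {
    if (!is.numeric(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(data[[col]]))))
      abort(paste0("non-numeric values in '", col, "' at row(s) ",
                   paste(head(bad, 5L), collapse = ", ")))
    }
  }
  if (anyNA(data) || !all(vapply(data, function(x) all(is.finite(x)), logical(1)))) {
    bad <- which(!stats::complete.cases(data) |
                   !is.finite(data$dose1) | !is.finite(data$dose2) |
                   !is.finite(data$response))
    abort(paste0("non-finite values at row(s) ", paste(head(bad, 5L), collapse = ", ")))
  }
  if (any(data$dose1 < 0) || any(data$dose2 < 0)) {
    abort("negative dose")
  }
  if (!any(data$dose1 == 0) || !any(data$dose2 == 0)) {
    abort("no monotherapy data: need rows with dose1 = 0 and rows with dose2 = 0")
  }
  structure(
    data,
    class = c("dose_response", class(data)),
    drug1 = drug1, drug2 = drug2, dose_unit = dose_unit,
    response_scale = response_scale, direction = direction
  )
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(
    "<dose_response> %s x %s, %d points (%s scale, %s), %d x %d design\n",
    attr(x, "drug1"), attr(x, "drug2"), nrow(x),
    attr(x, "response_scale"), attr(x, "direction"),
    length(unique(x$dose1)), length(unique(x$dose2))
  ))
  NextMethod()
}

dr_attrs <- function(data) {
  list(
    drug1 = attr(data, "drug1") %||% "drug1",
    drug2 = attr(data, "drug2") %||% "drug2",
    dose_unit = attr(data, "dose_unit") %||% "conc",
    response_scale = attr(data, "response_scale") %||% "percent",
    direction = attr(data, "direction") %||% "inhibitory"
  )
}

#' Read a dose-response matrix from CSV
#'
#' Two dialects are supported. `"long"`: a header line `dose1,dose2,response`
#' followed by one row per well. `"wide"`: a checkerboard matrix whose first
#' row holds the drug-2 doses, whose first column holds the drug-1 doses, and
#' whose top-left cell is ignored; rows are drug-1 doses, columns drug-2
#' doses. Files are UTF-8 with `.` as decimal separator.
#'
#' @param path Path to a CSV file.
#' @param format `"long"` or `"wide"`.
#' @inheritParams dose_response
#' @return A [dose_response] tibble.
#' @export
read_dose_response <- function(path, format = c("long", "wide"),
                               drug1 = "drug1", drug2 = "drug2",
                               dose_unit = "conc",
                               response_scale = c("percent", "fraction"),
                               direction = c("inhibitory", "stimulatory")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "long") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (!all(c("dose1", "dose2", "response") %in% names(raw))) {
      abort("long format requires columns dose1, dose2, response")
    }
    parsed <- dplyr::mutate(raw, dplyr::across(
      dplyr::all_of(c("dose1", "dose2", "response")),
      ~ suppressWarnings(as.numeric(.x))
    ))
    bad <- which(!stats::complete.cases(parsed[c("dose1", "dose2", "response")]))
    if (length(bad) > 0) {
      abort(paste0("non-numeric cell at data row(s) ", paste(head(bad, 5L), collapse = ", ")))
    }
    df <- parsed[c("dose1", "dose2", "response")]
  } else {
    m <- as.matrix(readr::read_csv(path, col_names = FALSE,
                                   col_types = readr::cols(.default = readr::col_character()),
                                   progress = FALSE))
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    num[1, 1] <- 0 # corner cell carries no data
    if (anyNA(num)) {
      bad <- which(apply(is.na(num), 1, any))
      abort(paste0("non-numeric cell at row(s) ", paste(head(bad, 5L), collapse = ", ")))
    }
    d1 <- num[-1, 1]
    d2 <- num[1, -1]
    resp <- num[-1, -1, drop = FALSE]
    df <- tibble(
      dose1 = rep(d1, times = length(d2)),
      dose2 = rep(d2, each = length(d1)),
      response = as.vector(resp)
    )
  }
  dose_response(df, drug1 = drug1, drug2 = drug2, dose_unit = dose_unit,
                response_scale = response_scale, direction = direction)
}

#' Write a dose-response data set to long-format CSV
#'
#' @param data A [dose_response] tibble (or any data frame with
#'   `dose1,dose2,response`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(data, path) {
  readr::write_csv(as_tibble(data)[c("dose1", "dose2", "response")], path,
                   progress = FALSE)
  invisible(path)
}

#' Build a prediction grid over the dose plane
#'
#' Constructs the dense grid of test points on which the GP surface, the
#' Hand null reference and all volume integrals are evaluated. With
#' `spacing = "log1p"` (default) the `n_per_axis` points per axis are equally
#' spaced in the warped coordinate u = log(1 + x / l), the same coordinate the
#' logarithmic kernel operates in, so grid resolution follows the kernel's
#' notion of distance; with `"linear"` they are equally spaced in dose. In
#' either case the grid spans \[0, max design dose\] and every distinct design
#' dose is snapped exactly onto its nearest grid point, so observed doses are
#' always grid nodes.
#'
#' @param data A [dose_response] data set (defines the design doses).
#' @param n_per_axis Number of grid points per axis (default 101).
#' @param lengthscales Length-2 numeric, the kernel length scales `(l1, l2)`
#'   used by the log1p warp. Ignored for linear spacing.
#' @param spacing `"log1p"` or `"linear"`.
#' @return A `dose_grid` object: list with numeric axes `axis1`, `axis2`
#'   (increasing, starting at 0) and the spacing used.
#' @export
dose_grid <- function(data, n_per_axis = 101, lengthscales = NULL,
                      spacing = c("log1p", "linear")) {
  spacing <- match.arg(spacing)
  if (n_per_axis < 2) abort("n_per_axis must be at least 2")
  d1 <- sort(unique(data$dose1))
  d2 <- sort(unique(data$dose2))
  if (n_per_axis < max(length(d1), length(d2))) {
    abort("n_per_axis must be at least the number of distinct design doses")
  }
  if (spacing == "log1p") {
    if (is.null(lengthscales)) lengthscales <- c(max(d1) / 2, max(d2) / 2)
    ax1 <- log1p_axis(max(d1), n_per_axis, lengthscales[1])
    ax2 <- log1p_axis(max(d2), n_per_axis, lengthscales[2])
  } else {
    ax1 <- seq(0, max(d1), length.out = n_per_axis)
    ax2 <- seq(0, max(d2), length.out = n_per_axis)
  }
  structure(
    list(axis1 = snap_axis(ax1, d1), axis2 = snap_axis(ax2, d2),
         spacing = spacing,
         lengthscales = if (spacing == "log1p") lengthscales else NULL),
    class = "dose_grid"
  )
}

# equally spaced in u = log(1 + x/l), mapped back by x = l (exp(u) - 1)
log1p_axis <- function(dmax, n, l) {
  stopifnot(l > 0)
  u <- seq(0, log1p(dmax / l), length.out = n)
  x <- l * expm1(u)
  x[1] <- 0
  x[n] <- dmax
  x
}

# replace the grid point nearest each design dose by the exact design dose
snap_axis <- function(axis, design) {
  for (d in design) {
    i <- which.min(abs(axis - d)) # ties -> lower index (which.min rule)
    axis[i] <- d
  }
  if (is.unsorted(axis, strictly = TRUE)) axis <- sort(unique(axis))
  axis
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d nodes, %s spacing, span [0, %g] x [0, %g]\n",
              length(x$axis1), length(x$axis2), x$spacing,
              max(x$axis1), max(x$axis2)))
  invisible(x)
}

#' All nodes of a prediction grid as a tibble
#'
#' @param grid A [dose_grid].
#' @return Tibble with columns `dose1`, `dose2`; drug-1 dose varies fastest.
#' @export
grid_points <- function(grid) {
  tibble(
    dose1 = rep(grid$axis1, times = length(grid$axis2)),
    dose2 = rep(grid$axis2, each = length(grid$axis1))
  )
}
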