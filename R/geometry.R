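#' Width-length relation of an elliptic wound
#'
#' Natural wounds are often elongated lacerations that are well described as
#' ellipses whose shape (aspect) stays constant while they heal. For such
#' wounds only the surface area may be recorded, and the minor-axis width --
#' the quantity healing distances are measured along -- has to be recovered
#' from the area. The link is an empirical linear relation between width
#' `W` (mm) and length `L` (mm) at the first observation day, `W = a * L + b`.
#'
#' @param a Dimensionless slope of width on length; must be positive (wider
#'   wounds are longer in this wound population).
#' @param b Intercept in mm. Negative values are physically dubious and
#'   trigger a warning, not an error.
#' @param residual_sd Residual standard deviation of the fit (mm), if known.
#' @param n_points Number of day-one wounds the relation was fitted on.
#'
#' @return An object of class `ellipse_relation`.
#' @seealso [fit_width_length_relation()], [width_from_area()]
#' @export
#' @examples
#' ellipse_relation(0.121, 3.963)
ellipse_relation <- function(a, b, residual_sd = NA_real_, n_points = NA_integer_) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0) {
    stop_user("`a` must be a single positive finite number, got %s", format(a)[1])
  }
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b)) {
    stop_user("`b` must be a single finite number")
  }
  if (b < 0) {
    warn("width-length intercept `b` is negative; the relation is not physically meaningful at small lengths")
  }
  structure(
    list(a = as.numeric(a), b = as.numeric(b),
         residual_sd = as.numeric(residual_sd),
         n_points = as.integer(n_points)),
    class = "ellipse_relation"
  )
}

#' @export
print.ellipse_relation <- function(x, ...) {
  cat(sprintf("<ellipse_relation>  W = %.4g * L + %.4g  (mm)\n", x$a, x$b))
  if (is.finite(x$residual_sd)) {
    cat(sprintf("  residual sd %.4g mm on %s day-one wounds\n",
                x$residual_sd, x$n_points))
  }
  invisible(x)
}

#' @export
#' @method tidy ellipse_relation
tidy.ellipse_relation <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
#' @method glance ellipse_relation
glance.ellipse_relation <- function(x, ...) {
  tibble(a = x$a, b = x$b, residual_sd = x$residual_sd, n_points = x$n_points)
}

#' Area of an elliptic wound from its axes
#'
#' `S = pi * L * W / 4` for an ellipse with major axis `L` and minor axis `W`
#' (both full axes, in mm). A circle of diameter `d` is the special case
#' `L = W = d`.
#'
#' @param length Major axis in mm (vectorised).
#' @param width Minor axis in mm (vectorised, recycled against `length`).
#' @return Areas in mm².
#' @export
#' @examples
#' ellipse_area(40, 40)   # 40 mm circular wound, ~1256.6 mm^2
ellipse_area <- function(length, width) {
  if (!is.numeric(length) || !is.numeric(width)) {
    stop_user("axes must be numeric")
  }
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length < 0) || any(width < 0)) {
    stop_user("axes must be finite and non-negative")
  }
  pi * length * width / 4
}

#' Fit the day-one width-length relation
#'
#' Ordinary least-squares regression of wound width on wound length over a set
#' of wounds measured at their first observation day. The fitted coefficients
#' define the [ellipse_relation()] used to recover widths from areas.
#'
#' @param data Data frame with one row per day-one wound.
#' @param length,width Columns holding the major and minor axes in mm
#'   (tidy evaluation; defaults `length_mm`, `width_mm`).
#' @return An [ellipse_relation()] carrying the residual SD and point count.
#' @export
#' @examples
#' d <- tibble::tibble(length_mm = c(10, 20, 30), width_mm = 0.5 * c(10, 20, 30) + 2)
#' fit_width_length_relation(d)
fit_width_length_relation <- function(data, length = length_mm, width = width_mm) {
  L <- dplyr::pull(data, {{ length }})
  W <- dplyr::pull(data, {{ width }})
  n_pts <- base::length(L)
  if (n_pts < 2) {
    stop_user("need at least 2 day-one wounds to fit the width-length relation, got %d", n_pts)
  }
  if (dplyr::n_distinct(L) < 2) {
    stop_user("all wound lengths are identical; the width-length relation is not identifiable")
  }
  fit <- lm(W ~ L)
  cf <- coef(fit)
  rss <- sum(fit$residuals^2)
  df <- n_pts - 2L
  resid_sd <- if (df > 0) sqrt(rss / df) else 0
  ellipse_relation(a = unname(cf[2L]), b = unname(cf[1L]),
                   residual_sd = resid_sd, n_points = n_pts)
}

#' Recover wound width from wound area
#'
#' Substituting the day-one relation `L = (W - b) / a` into the ellipse area
#' `S = pi * L * W / 4` gives the quadratic `W^2 - b*W - 4*a*S/pi = 0`. For
#' `S > 0` the two roots have negative product, so exactly one is positive;
#' that root, `W = (b + sqrt(b^2 + 16*a*S/pi)) / 2`, is returned.
#'
#' @details
#' Some sources typeset this quadratic with the roles of `a` and `b`
#' interchanged (`W^2 - a*W - 4*b*S/pi = 0`), which is not consistent with the
#' substitution above. The consistent form is the default; the alternative
#' coefficient arrangement is available via `quadratic = "printed"` for
#' sensitivity analysis only.
#'
#' At `S = 0` the roots are `{0, b}` and the model's limit as `L -> 0` is
#' `W = b`, which is returned with a warning: a fully healed wound should be
#' encoded as healing distance equal to the reference size, not pushed through
#' the inversion.
#'
#' @param area Wound areas in mm² (vectorised, all `>= 0`).
#' @param relation An [ellipse_relation()].
#' @param quadratic `"derived"` (consistent form, default) or `"printed"`
#'   (swapped coefficient arrangement, for sensitivity analysis).
#' @return Widths in mm; always `>= relation$b` under `"derived"`.
#' @export
#' @examples
#' rel <- ellipse_relation(0.121, 3.963)
#' width_from_area(391.83, rel)   # ~10 mm
width_from_area <- function(area, relation, quadratic = c("derived", "printed")) {
  quadratic <- match.arg(quadratic)
  stopifnot(inherits(relation, "ellipse_relation"))
  if (!is.numeric(area) || any(!is.finite(area))) {
    stop_user("`area` must be finite numeric")
  }
  if (any(area < 0)) {
    stop_user("negative wound area supplied (min %.4g); areas are mm^2 and must be >= 0", min(area))
  }
  if (any(area == 0)) {
    warn(paste0("area 0 maps to the L -> 0 limit W = b; fully healed wounds are better ",
                "encoded as healing distance = reference size than run through the inversion"))
  }
  a <- relation$a
  b <- relation$b
  if (quadratic == "derived") {
    (b + sqrt(b^2 + 16 * a * area / pi)) / 2
  } else {
    (a + sqrt(a^2 + 16 * b * area / pi)) / 2
  }
}

#' Implied wound length from width
#'
#' Inverse of the day-one relation: `L = (W - b) / a`. Defined only for
#' `W >= b`; smaller widths would imply a negative major axis.
#'
#' @param width Widths in mm (vectorised).
#' @param relation An [ellipse_relation()].
#' @return Lengths in mm.
#' @export
length_from_width <- function(width, relation) {
  stopifnot(inherits(relation, "ellipse_relation"))
  if (!is.numeric(width) || any(!is.finite(width))) {
    stop_user("`width` must be finite numeric")
  }
  if (any(width < relation$b)) {
    stop_user("width %.4g mm is below the relation intercept b = %.4g mm; the model implies a negative length",
              min(width), relation$b)
  }
  (width - relation$b) / relation$a
}

#' Serialize / restore a width-length relation
#'
#' Writes the coefficients as a small JSON block `{a, b, residual_sd,
#' n_points}` so a fitted relation can be reused across runs.
#'
#' @param relation An [ellipse_relation()].
#' @param path File path.
#' @return `write_relation()` returns `path` invisibly; `read_relation()`
#'   returns an [ellipse_relation()].
#' @export
write_relation <- function(relation, path) {
  stopifnot(inherits(relation, "ellipse_relation"))
  jsonlite::write_json(unclass(relation), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_relation
#' @export
read_relation <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ellipse_relation(x$a, x$b,
                   residual_sd = x$residual_sd %||% NA_real_,
                   n_points = x$n_points %||% NA_integer_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
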