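#' Octant geometry of the interpersonal circumplex
#'
#' The interpersonal circumplex (IPC) divides the interpersonal plane into
#' eight 45-degree octants labelled with two-letter codes. Angles are measured
#' counterclockwise with communion (warmth/affiliation) on the positive x-axis
#' and agency (dominance) on the positive y-axis, so PA (dominant) sits at 90
#' degrees and LM (warm) at 360 degrees. All profile and scoring functions in
#' the package order octants by this geometry.
#'
#' @param codes Character vector of octant labels, in profile order.
#' @param angles Named numeric vector of angular midpoints in degrees, one per
#'   code, each in `(0, 360]`.
#'
#' @return An object of class `octant_geometry`: a list with elements `codes`
#'   and `angles`.
#' @examples
#' geom <- octant_geometry()
#' geom$angles[["DE"]] # 180, the cold octant
#' @export
octant_geometry <- function(codes = c("PA", "BC", "DE", "FG", "HI", "JK", "LM", "NO"),
                            angles = c(PA = 90, BC = 135, DE = 180, FG = 225,
                                       HI = 270, JK = 315, LM = 360, NO = 45)) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("octant codes must be unique", call. = FALSE)
  if (!all(codes %in% names(angles))) {
    stop("every octant code needs an angle", call. = FALSE)
  }
  angles <- angles[codes]
  if (any(angles <= 0 | angles > 360)) {
    stop("octant angles must lie in (0, 360]", call. = FALSE)
  }
  if (length(codes) == 8L) {
    # equal 45-degree spacing on the circle
    sorted <- sort(angles %% 360)
    gaps <- diff(c(sorted, sorted[1] + 360))
    if (any(abs(gaps - 45) > 1e-8)) {
      stop("the 8 octant angles must be equally spaced at 45 degrees", call. = FALSE)
    }
  }
  structure(list(codes = codes, angles = angles), class = "octant_geometry")
}

#' @export
print.octant_geometry <- function(x, ...) {
  cat("<octant_geometry> ", length(x$codes), " octants\n", sep = "")
  print(x$angles)
  invisible(x)
}

## --- circular helpers (degrees) ---------------------------------------------

deg2rad <- function(x) x * pi / 180

#' Wrap an angle into [0, 360)
#' @param theta Angle(s) in degrees.
#' @return Angle(s) in `[0, 360)`.
#' @export
wrap_360 <- function(theta) theta %% 360

#' Wrap a signed angular difference into (-180, 180]
#' @param theta Angle(s) in degrees.
#' @return Angle(s) in `(-180, 180]`.
#' @export
wrap_180 <- function(theta) {
  out <- theta %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

#' Signed circular difference a - b in (-180, 180]
#' @param a,b Angles in degrees.
#' @return Signed difference in degrees.
#' @export
angle_diff <- function(a, b) wrap_180(a - b)

#' Does a circular interval contain an angle?
#'
#' The interval runs counterclockwise from `lower` to `upper` and may wrap
#' through 0/360 (i.e. `lower` may numerically exceed `upper`).
#' @param theta Angle in degrees.
#' @param lower,upper Interval bounds in degrees.
#' @return Logical.
#' @export
angle_in_interval <- function(theta, lower, upper) {
  theta <- wrap_360(theta); lower <- wrap_360(lower); upper <- wrap_360(upper)
  if (isTRUE(all.equal(lower, upper))) return(isTRUE(all.equal(theta, lower)))
  if (lower <= upper) theta >= lower & theta <= upper else theta >= lower | theta <= upper
}
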