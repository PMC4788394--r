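# internal helpers shared across modules

# coerce to an n x 2 numeric matrix of planar points
as_points <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 2L) {
    x <- matrix(x, nrow = 1L)
  }
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 2L) {
    stop("`", arg, "` must be an n x 2 numeric matrix of (x, y) points",
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("`", arg, "` contains non-finite coordinates", call. = FALSE)
  }
  dimnames(x) <- list(NULL, c("x", "y"))
  x
}

# a single planar point as length-2 numeric
as_point <- function(x, arg = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (length(x) != 2L || !all(is.finite(x))) {
    stop("`", arg, "` must be a finite (x, y) pair", call. = FALSE)
  }
  x
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) == 0L || anyNA(theta)) {
    stop("`theta` must be numeric with no missing values", call. = FALSE)
  }
  if (any(theta < 0 | theta > 1)) {
    stop("`theta` must lie in [0, 1]; got values outside the domain",
         call. = FALSE)
  }
  as.numeric(theta)
}

check_positive <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("`", arg, "` must be a single positive finite number", call. = FALSE)
  }
  as.numeric(x)
}

row_norms <- function(m) sqrt(rowSums(m * m))

vnorm <- function(v) sqrt(sum(v * v))

# signed polygon area (shoelace); > 0 for counterclockwise in standard (x, y)
signed_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}
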