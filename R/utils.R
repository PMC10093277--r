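#' @useDynLib petuq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif rbinom rexp sd var median pchisq
#'   pnorm setNames aggregate predict
#' @importFrom utils head tail write.csv read.csv
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a finite numeric scalar", name)
  }
  if (x < lower || x > upper) {
    stopf("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

assert_mask <- function(mask, classes = 0:2) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stopf("label mask must be a 3D array")
  }
  vals <- unique(as.vector(mask))
  if (!all(vals %in% classes)) {
    stopf("label mask contains classes outside {%s}",
          paste(classes, collapse = ","))
  }
  invisible(mask)
}

#' Voxel spacing of a volume or mask
#'
#' Spacing in mm per axis is carried as an attribute; defaults to 1 mm
#' isotropic when absent.
#'
#' @param x a 3D array.
#' @return numeric length-3 spacing in mm.
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) sp <- c(1, 1, 1)
  as.numeric(sp)
}

#' @rdname voxel_spacing
#' @param value numeric length-3 spacing in mm.
#' @export
`voxel_spacing<-` <- function(x, value) {
  stopifnot(length(value) == 3L, all(value > 0))
  attr(x, "spacing") <- as.numeric(value)
  x
}

voxel_volume <- function(x) prod(voxel_spacing(x))
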