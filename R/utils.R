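# internal helpers shared across modules

#' @import data.table
NULL

.datatable.aware <- TRUE

# Integer voxel indices for points at a given edge size, anchored at the
# cloud's minimum corner. Anchoring matters: box counting and decimation are
# origin-sensitive, so the same anchor is used everywhere.
voxel_index <- function(x, y, z, edge, origin = NULL) {
  if (is.null(origin)) origin <- c(min(x), min(y), min(z))
  data.table(
    ix = as.integer(floor((x - origin[1]) / edge + 1e-9)),
    iy = as.integer(floor((y - origin[2]) / edge + 1e-9)),
    iz = as.integer(floor((z - origin[3]) / edge + 1e-9))
  )
}

#' Derive a reproducible RNG stream seed
#'
#' Deterministic 31-bit seed hashed from a master seed and any number of
#' labels (e.g. plot id and survey day), so every plot/survey pair gets an
#' independent, individually reproducible RNG stream.
#'
#' @param master integer master seed.
#' @param ... labels folded into the hash (coerced to character).
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(master, ...) {
  label <- paste(c(master, ...), collapse = "|")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

# sample sd / mean; the coefficient of variation used for both the canopy
# height raster and the seasonal series (n - 1 denominator throughout)
cv <- function(x) stats::sd(x) / mean(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
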