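# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never disturbs the
#' caller's random stream. All stochastic operations in the package route
#' through this helper, which is what makes them reproducible under an
#' explicit `seed` argument.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range. Keeps independent stages of a pipeline on
# independent, reproducible streams.
derive_seed <- function(seed, stream) {
  h <- digest::digest(list(as.integer(seed), as.character(stream)),
                      algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483647L) + 1L
}

# Calendar-month arithmetic with day-of-month clamping:
# add_months("2020-03-31", -1) is "2020-02-29".
add_months <- function(date, k) {
  stopifnot(inherits(date, "Date"))
  lt <- as.POSIXlt(date)
  m0 <- lt$year * 12L + lt$mon + as.integer(k)
  y <- m0 %/% 12L
  m <- m0 %% 12L
  last_day <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m + 1L]
  leap <- (m == 1L) & ((y + 1900L) %% 4L == 0L &
                         ((y + 1900L) %% 100L != 0L | (y + 1900L) %% 400L == 0L))
  last_day[leap] <- 29L
  lt$year <- y
  lt$mon <- m
  lt$mday <- pmin(lt$mday, last_day)
  as.Date(lt)
}

as_date_strict <- function(x, what = "date") {
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  bad <- is.na(d) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(utils::head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  d
}

# Largest-remainder (Hamilton) apportionment of `n` into parts proportional
# to `weights`; used for stratified allocation in sampling and splitting.
allocate_counts <- function(n, weights, capacity = NULL) {
  stopifnot(n >= 0, all(weights >= 0))
  if (sum(weights) == 0) return(rep(0L, length(weights)))
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  alloc <- as.integer(base)
  if (!is.null(capacity)) {
    # shift any overflow to strata with spare room, preserving the total
    overflow <- pmax(alloc - capacity, 0L)
    alloc <- pmin(alloc, capacity)
    short <- sum(overflow)
    while (short > 0L) {
      spare <- capacity - alloc
      if (all(spare <= 0L)) break
      i <- which.max(spare)
      take <- min(short, spare[i])
      alloc[i] <- alloc[i] + take
      short <- short - take
    }
  }
  alloc
}

is_scalar_character <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_user <- function(fmt, ...) {
  stop(structure(class = c("notesieve_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}
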