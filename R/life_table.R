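#' Parametric background-mortality life table
#'
#' Builds an annual all-cause mortality table over integer ages 0-100 from a
#' Gompertz-Makeham hazard on the probability scale,
#' `qx(a) = min(1, c + b * exp(g * a))`: an age-independent (Makeham)
#' component `c` plus an exponentially age-increasing (Gompertz) component.
#' The default coefficients were chosen once so that life expectancy at birth
#' is about 75 years, the all-cause mortality level of China around 2011;
#' the packaged CSV `life_table_cn2011_approx.csv` is generated from these
#' defaults and is an approximation, not an official life table.
#'
#' @param c Makeham constant (annual probability).
#' @param b Gompertz level coefficient (annual probability scale).
#' @param g Gompertz log-slope (per year of age).
#' @return A data frame of class `escc_life_table` with columns `age`
#'   (0-100) and `qx`.
#' @seealso [default_life_table()], [life_expectancy()]
#' @export
#' @examples
#' lt <- make_life_table()
#' life_expectancy(lt)
make_life_table <- function(c = 0.0015, b = 2e-5, g = 0.10) {
  if (any(!is.finite(c(c, b, g))) || c < 0 || b < 0) {
    stop("invalid life-table coefficients", call. = FALSE)
  }
  age <- 0:100
  qx <- pmin(1, c + b * exp(g * age))
  if (any(qx < 0 | qx > 1)) stop("generated qx outside [0, 1]", call. = FALSE)
  structure(data.frame(age = age, qx = qx),
            class = c("escc_life_table", "data.frame"))
}

#' Packaged approximate Chinese 2011 life table
#'
#' Reads the life table shipped with the package (see [make_life_table()]
#' for its construction).
#'
#' @return An `escc_life_table` data frame.
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_cn2011_approx.csv",
                              package = "esccsim"))
}

#' Read and write life tables as CSV
#'
#' The interchange format is a CSV with header `age,qx` and one row per
#' integer age 0-100.
#'
#' @param path File path.
#' @param life_table An `escc_life_table` (or compatible data frame).
#' @return `read_life_table()` returns an `escc_life_table`;
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path)
  as_life_table(lt)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(life_table, path) {
  lt <- as_life_table(life_table)
  utils::write.csv(lt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_life_table
#' @export
as_life_table <- function(life_table) {
  if (!all(c("age", "qx") %in% names(life_table))) {
    stop("life table needs columns 'age' and 'qx'", call. = FALSE)
  }
  lt <- as.data.frame(life_table)[c("age", "qx")]
  lt <- lt[order(lt$age), ]
  if (!all(15:100 %in% lt$age)) {
    stop("life table must cover every integer age 15-100", call. = FALSE)
  }
  if (any(!is.finite(lt$qx)) || any(lt$qx < 0 | lt$qx > 1)) {
    stop("life-table qx outside [0, 1]", call. = FALSE)
  }
  structure(lt, class = c("escc_life_table", "data.frame"))
}

#' Life expectancy at birth implied by a life table
#'
#' Sums the survival curve implied by `qx` (half-year credit in the year of
#' death).  Used to sanity-check the packaged parametric table.
#'
#' @param life_table An `escc_life_table`.
#' @return Life expectancy at birth, in years.
#' @export
life_expectancy <- function(life_table) {
  lt <- as_life_table(life_table)
  q <- lt$qx[lt$age >= 0]
  0.5 + sum(cumprod(1 - q))
}

# annual death probability at integer ages, as a lookup vector indexed age+1
qx_lookup <- function(life_table) {
  lt <- as_life_table(life_table)
  q <- numeric(101)
  q[lt$age + 1] <- lt$qx
  q
}
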