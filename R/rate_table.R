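# Temperature-grid rate computation and the TSV rate table.

#' Compute rate constants over a temperature grid
#'
#' Runs TST (and, when the system carries a GTS series and
#' `method = "CVT"`, variational TST) at every temperature, with optional
#' Eckart tunneling.
#'
#' @param system A [reaction_system()].
#' @param temperatures Numeric vector of temperatures in K, strictly
#'   increasing.
#' @param method `"TST"` or `"CVT"`.
#' @param hr_model Torsion model: `"HO"`, `"PG"` or `"AS"`.
#' @param eckart Include the Eckart transmission coefficient?  Requires
#'   product records (for the reverse barrier) unless `barrier` is given.
#' @param barrier Optional [eckart_barrier()] to use instead of deriving
#'   one from the system (the default barrier is evaluated at the saddle
#'   point, not the variational TS).
#' @param P Pressure in atm.
#' @return Object of class `rate_result`: a data frame `table` with one
#'   row per temperature (`T`, `dG_TST_1M`, `k_TST`, and when applicable
#'   `s_star`, `dG_CVT_1M`, `k_CVT`, `kappa_Eckart`, the
#'   tunneling-corrected products and the recrossing factor), plus
#'   metadata (`units`, `method`, `hr_model`, `molecularity`,
#'   `sigma_rx`).
#' @export
compute_rates <- function(system, temperatures = 298.15,
                          method = c("TST", "CVT"), hr_model = "HO",
                          eckart = FALSE, barrier = NULL, P = 1) {
  method <- match.arg(method)
  stopifnot(all(temperatures > 0))
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperature grid must be strictly increasing")
  if (method == "CVT" && !length(system$gts_series))
    stop("CVT requested but the system has no GTS series")
  if (eckart && is.null(barrier)) barrier <- eckart_barrier(system)

  rows <- lapply(temperatures, function(T) {
    kt <- k_tst(system, T, hr_model, P)
    row <- list(T = T,
                dG_TST_1M = attr(kt, "activation")$dG_1M,
                k_TST = as.numeric(kt))
    if (method == "CVT") {
      cv <- k_cvt(system, T, hr_model, P)
      row$s_star <- cv$s_star
      row$dG_CVT_1M <- attr(cv$k, "activation")$dG_1M
      row$k_CVT <- as.numeric(cv$k)
      row$recrossing <- row$k_TST / row$k_CVT
    }
    if (eckart) {
      row$kappa_Eckart <- eckart_kappa(barrier, T)
      row$k_TST_kappa <- row$k_TST * row$kappa_Eckart
      if (!is.null(row$k_CVT)) row$k_CVT_kappa <- row$k_CVT * row$kappa_Eckart
    }
    row
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  units <- if (system$molecularity == 2L) "cm^3 molecule^-1 s^-1" else "s^-1"
  structure(list(table = tab, units = units, method = method,
                 hr_model = hr_model, molecularity = system$molecularity,
                 sigma_rx = symmetry_factor(system), P = P),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> %s/%s, %d temperature(s), k in %s\n",
              x$method, x$hr_model, nrow(x$table), x$units))
  print(x$table, digits = 5)
  invisible(x)
}

#' Write a rate table
#'
#' Tab-separated table with one row per temperature.  Rate-constant
#' columns are written at full precision (12+ significant digits) and each
#' is accompanied by a `*_disp` column rounded to two significant figures
#' in scientific notation, the style rate-constant tables are usually
#' printed in.  Header comment lines record the units, method, torsion
#' model and symmetry factor.
#'
#' @param result A `rate_result` from [compute_rates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(result, path) {
  stopifnot(inherits(result, "rate_result"))
  tab <- result$table
  if (nrow(tab) < 1) stop("rate result has no temperatures")
  for (col in intersect(c("k_TST", "k_CVT", "k_TST_kappa", "k_CVT_kappa"),
                        names(tab)))
    tab[[paste0(col, "_disp")]] <- sprintf("%.1e", tab[[col]])
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(v) sprintf("%.14e", v))
  hdr <- c(
    sprintf("# k units: %s", result$units),
    sprintf("# method: %s  hr_model: %s  sigma_Rx: %g  P: %g atm",
            result$method, result$hr_model, result$sigma_rx, result$P),
    "# T in K, dG in kcal/mol (1 M standard state), s_star in amu^1/2 bohr")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a rate table
#'
#' Inverse of [write_rate_table()]; numeric columns round-trip to full
#' double precision.
#'
#' @param path Path to a rate table file.
#' @return Data frame of the table body with the `units` comment attached
#'   as attribute `units`.
#' @export
read_rate_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  u <- sub("^# k units: ", "", hdr[startsWith(hdr, "# k units: ")])
  attr(tab, "units") <- if (length(u)) u else NA_character_
  tab
}
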