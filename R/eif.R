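# The *.eif run-control dialect: line-oriented `KEY value` pairs with
# case-insensitive keys.  Recognized keywords:
#   METHOD TST|CVT            REACT1/REACT2/TS/PROD1/PROD2 <file>
#   RXSYM <number>            IRC <file> [<file> ...]
#   PATHPOINTS <dir>          PATHPOINTS_INP <template file>
#   HINDROT PG|AS             ECKART TRUE|FALSE
#   TEMPERATURE <K> [...]     PRESSURE <atm>
#   RED_MOM_INERT_x / TORFREQ_x / TORNSYM_x / TORBARRIER_x  (x a species
#   tag: R1, R2, RC, TS, PC, P1, P2)
# Unknown keys are collected and reported with a warning, never silently
# dropped.

#' Parse a run-control (*.eif) file
#'
#' @param path Path to the key-value run-control file.
#' @return Object of class `eif_config`: `method`, `files` (named species
#'   file references), `rxsym`, `irc_files`, `pathpoints_dir`,
#'   `pathpoints_template`, `hindrot`, `eckart`, `temperatures`,
#'   `pressure`, `torsion_params` (per-species list of `I_r`, `nu_tau`,
#'   `sigma_tau`, `V0`), and `unknown` (unrecognized keys).
#' @export
parse_eif <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("METHOD missing: empty run-control file")
  key <- toupper(regmatches(lines, regexpr("^\\S+", lines)))
  val <- trimws(substring(lines, nchar(key) + 1L))

  take1 <- function(k) { i <- which(key == k); if (length(i)) val[i[length(i)]] else NULL }
  known <- c("METHOD", "REACT1", "REACT2", "TS", "PROD1", "PROD2", "RXSYM",
             "IRC", "PATHPOINTS", "PATHPOINTS_INP", "HINDROT", "ECKART",
             "TEMPERATURE", "PRESSURE")
  species_tags <- c("R1", "R2", "RC", "TS", "PC", "P1", "P2")
  tor_re <- paste0("^(RED_MOM_INERT|TORFREQ|TORNSYM|TORBARRIER)_(",
                   paste(species_tags, collapse = "|"), ")$")
  is_tor <- grepl(tor_re, key)
  unknown <- setdiff(unique(key[!is_tor]), known)
  if (length(unknown))
    warning("unrecognized run-control keyword(s), ignored: ",
            paste(unknown, collapse = ", "))

  method <- take1("METHOD")
  if (is.null(method)) stop("METHOD missing from run-control file")
  method <- toupper(method)
  if (!method %in% c("TST", "CVT"))
    stop("METHOD must be TST or CVT, got ", method)

  rxsym <- take1("RXSYM")
  if (!is.null(rxsym)) {
    rxsym <- suppressWarnings(as.numeric(rxsym))
    if (is.na(rxsym)) stop("RXSYM must be numeric")
  }

  irc_files <- character()
  for (i in which(key == "IRC"))
    irc_files <- c(irc_files, strsplit(val[i], "\\s+")[[1]])

  hindrot <- take1("HINDROT")
  if (!is.null(hindrot)) {
    hindrot <- toupper(hindrot)
    if (!hindrot %in% c("PG", "AS"))
      stop("HINDROT must be PG or AS, got ", hindrot)
  }

  temps <- take1("TEMPERATURE")
  temps <- if (is.null(temps)) 298.15 else
    as.numeric(strsplit(temps, "\\s+")[[1]])
  if (any(is.na(temps)) || any(temps <= 0))
    stop("TEMPERATURE grid must be positive numbers")
  if (is.unsorted(temps, strictly = TRUE))
    stop("TEMPERATURE grid must be strictly increasing")

  pressure <- take1("PRESSURE")
  pressure <- if (is.null(pressure)) 1 else as.numeric(pressure)

  tor <- list()
  for (i in which(is_tor)) {
    m <- regmatches(key[i], regexec(tor_re, key[i]))[[1]]
    field <- c(RED_MOM_INERT = "I_r", TORFREQ = "nu_tau",
               TORNSYM = "sigma_tau", TORBARRIER = "V0")[m[2]]
    sp <- m[3]
    if (is.null(tor[[sp]])) tor[[sp]] <- list()
    tor[[sp]][[field]] <- as.numeric(val[i])
  }

  files <- list(REACT1 = take1("REACT1"), REACT2 = take1("REACT2"),
                TS = take1("TS"), PROD1 = take1("PROD1"),
                PROD2 = take1("PROD2"))
  files <- files[!vapply(files, is.null, logical(1))]

  eck <- take1("ECKART")
  structure(list(
    method = method, files = files, rxsym = rxsym, irc_files = irc_files,
    pathpoints_dir = take1("PATHPOINTS"),
    pathpoints_template = take1("PATHPOINTS_INP"),
    hindrot = hindrot,
    eckart = !is.null(eck) && toupper(eck) %in% c("TRUE", "T", "YES", "1"),
    temperatures = temps, pressure = pressure,
    torsion_params = tor, unknown = unknown),
    class = "eif_config")
}

#' @export
print.eif_config <- function(x, ...) {
  cat(sprintf("<eif_config> METHOD %s%s\n", x$method,
              if (!is.null(x$hindrot)) paste0(", HINDROT ", x$hindrot) else ""))
  cat("  species files:", paste(names(x$files), collapse = " "), "\n")
  if (length(x$irc_files)) cat("  IRC:", paste(x$irc_files, collapse = " "), "\n")
  cat(sprintf("  %d temperature(s), P = %g atm\n",
              length(x$temperatures), x$pressure))
  invisible(x)
}
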