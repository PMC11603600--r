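# IRC profile tables: two-column delimited text (s in amu^1/2 bohr, V in
# hartree), one branch per file or a merged path.

#' Read IRC profile files into a merged path table
#'
#' Each file holds one IRC branch (or a merged path) as two numeric
#' columns `s`, `V` (hartree); `#` comment lines are ignored.  Branches
#' are merged with the transition state at `s = 0`, reactants at `s < 0`
#' and products at `s > 0`, and energies are re-zeroed to the reactant
#' asymptote.
#'
#' When branch files carry only unsigned `|s|` values, the branch whose
#' far endpoint has the lower energy is taken as the reactant side (its
#' `s` values are negated); pass `reactant_branch` to override the
#' heuristic.
#'
#' @param paths Character vector of 1 or 2 branch files.
#' @param e_reactants Electronic energy of the reactant asymptote in
#'   hartree (sum over reactants), used as the zero of `V`.  If `NULL`,
#'   the lower path endpoint is used with a message.
#' @param reactant_branch Optional index (1 or 2) forcing which file is
#'   the reactant-side branch when direction is ambiguous.
#' @return Object of class `irc_table`: data frame `points` with `s` and
#'   `V` (kcal/mol relative to reactants), plus `V_hartree` and the
#'   detected `step`.
#' @export
read_irc <- function(paths, e_reactants = NULL, reactant_branch = NULL) {
  stopifnot(length(paths) >= 1, length(paths) <= 2)
  branches <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("no such IRC file: ", p)
    d <- utils::read.table(p, col.names = c("s", "V"),
                           comment.char = "#", stringsAsFactors = FALSE)
    if (any(is.na(d$s)) || any(is.na(d$V)))
      stop("non-numeric IRC data in ", p)
    if (is.unsorted(d$s, strictly = TRUE) &&
        is.unsorted(rev(d$s), strictly = TRUE))
      stop("non-monotone s within IRC branch ", p)
    if (d$s[1] > d$s[nrow(d)]) d <- d[rev(seq_len(nrow(d))), ]
    d
  })

  if (length(branches) == 1L) {
    merged <- branches[[1]]
    if (min(merged$s) >= 0) {
      warning("single IRC branch: only one side of the path is present")
    }
  } else {
    b1 <- branches[[1]]; b2 <- branches[[2]]
    both_unsigned <- min(b1$s) >= 0 && min(b2$s) >= 0
    if (both_unsigned) {
      ri <- reactant_branch
      if (is.null(ri)) {
        # reactant side sits lower in energy after re-zeroing (default
        # heuristic; override with `reactant_branch`)
        end1 <- b1$V[nrow(b1)]; end2 <- b2$V[nrow(b2)]
        ri <- if (end1 <= end2) 1L else 2L
      }
      branches[[ri]]$s <- -branches[[ri]]$s
      b1 <- branches[[1]]; b2 <- branches[[2]]
    }
    if (max(b1$s) > min(b2$s) && max(b2$s) > min(b1$s)) {
      # allow the shared s = 0 point; anything more is an overlap
      ov1 <- b1$s[b1$s %in% b2$s]
      if (length(setdiff(ov1, 0)))
        stop("IRC branches overlap in s")
    }
    merged <- rbind(b1, b2)
    merged <- merged[!duplicated(merged$s), ]
    merged <- merged[order(merged$s), ]
  }

  if (!any(merged$s == 0)) stop("merged IRC path must contain s = 0")
  if (anyDuplicated(merged$s)) stop("duplicated s in merged IRC path")

  if (is.null(e_reactants)) {
    e_reactants <- min(merged$V[c(1, nrow(merged))])
    message("no reactant energy supplied; re-zeroing to the lower path endpoint")
  }
  V_rel <- (merged$V - e_reactants) * .pc$hartree_kcalmol
  structure(list(points = data.frame(s = merged$s, V = V_rel),
                 V_hartree = merged$V,
                 e_reactants = e_reactants,
                 step = stats::median(abs(diff(merged$s)))),
            class = "irc_table")
}

#' @export
print.irc_table <- function(x, ...) {
  cat(sprintf("<irc_table> %d points, s in [%.3f, %.3f], step ~ %.3g\n",
              nrow(x$points), min(x$points$s), max(x$points$s), x$step))
  invisible(x)
}

#' Minimum-energy path from an IRC table
#'
#' @param irc An [read_irc()] result.
#' @return An [mep_profile()] with `V` in kcal/mol relative to reactants.
#' @export
mep_from_irc <- function(irc) {
  stopifnot(inherits(irc, "irc_table"))
  mep_profile(irc$points$s, irc$points$V)
}
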