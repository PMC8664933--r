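#' Effective-population-size trajectories
#'
#' Holds an Ne point estimate per past generation (1-based, backwards in
#' time), optionally with confidence bounds, as emitted by IBD-based Ne
#' estimators. Units are diploid individuals exactly as printed by the
#' upstream tool; any rescaling (e.g. to reproducing pairs) is applied
#' downstream by the footprint model, never at read time.
#'
#' @param gen integer generations, contiguous from 1.
#' @param ne positive Ne point estimates.
#' @param lwr,upr optional confidence bounds bracketing `ne`.
#' @return data.frame of class `ne_trajectory`.
#' @export
ne_trajectory <- function(gen, ne, lwr = NULL, upr = NULL) {
  gen <- as.integer(gen)
  o <- order(gen)
  gen <- gen[o]; ne <- as.numeric(ne)[o]
  if (length(gen) == 0) stop("empty trajectory")
  if (!identical(gen, seq_len(max(gen)))) {
    gaps <- setdiff(seq_len(max(gen)), gen)
    stop("generations must be contiguous from 1; missing: ",
         paste(utils::head(gaps, 5), collapse = ", "))
  }
  if (any(!is.finite(ne)) || any(ne <= 0)) stop("Ne must be positive everywhere")
  d <- data.frame(gen = gen, ne = ne)
  if (!is.null(lwr)) {
    d$lwr <- as.numeric(lwr)[o]; d$upr <- as.numeric(upr)[o]
    if (any(d$lwr > d$ne | d$ne > d$upr))
      stop("confidence bounds must bracket the point estimate")
  }
  class(d) <- c("ne_trajectory", "data.frame")
  d
}

#' Read an Ne trajectory file
#'
#' Tab-delimited with a header; columns named `GEN` and `NE`
#' (case-insensitive) are required, optional `LWR-95%CI`/`UPR-95%CI`
#' (any names containing "lwr"/"upr") are used as confidence bounds, and
#' all other columns are ignored. This tolerant dialect accommodates the
#' exact header printed by IBDNe-style estimators.
#'
#' @param path file path.
#' @return an [ne_trajectory()].
#' @export
read_ne_trajectory <- function(path) {
  if (!file.exists(path)) stop("Ne trajectory file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  nm <- tolower(names(d))
  gi <- match("gen", nm); ni <- match("ne", nm)
  if (is.na(gi) || is.na(ni)) stop("trajectory file must have GEN and NE columns")
  li <- grep("lwr", nm)[1]; ui <- grep("upr", nm)[1]
  if (!is.na(li) && !is.na(ui))
    ne_trajectory(d[[gi]], d[[ni]], d[[li]], d[[ui]])
  else
    ne_trajectory(d[[gi]], d[[ni]])
}

#' @rdname read_ne_trajectory
#' @param traj an [ne_trajectory()].
#' @export
write_ne_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ne_trajectory"))
  out <- data.frame(GEN = traj$gen, NE = format(traj$ne, scientific = FALSE, trim = TRUE))
  if (!is.null(traj$lwr)) {
    out[["LWR-95%CI"]] <- format(traj$lwr, scientific = FALSE, trim = TRUE)
    out[["UPR-95%CI"]] <- format(traj$upr, scientific = FALSE, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
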