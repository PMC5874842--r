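#' Compound descriptors
#'
#' A compound descriptor captures everything the screening pipeline needs to
#' know about one drug or polymer: structural group counts per contribution
#' scheme (either directly, or per repeat unit with mole fractions for
#' copolymers), molecular weight, true density (polymers), and the thermal
#' properties used downstream (glass transition, melting point).
#'
#' @param path Path to a YAML descriptor file.
#' @return A `compound` object (a named list).
#' @export
read_compound <- function(path) {
  x <- yaml::read_yaml(path)
  validate_compound(x, path)
  structure(x, class = "compound")
}

validate_compound <- function(x, path = "<descriptor>") {
  req <- c("name", "abbreviation", "role", "mw")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop(path, ": missing field(s): ", paste(miss, collapse = ", "))
  if (!x$role %in% c("drug", "polymer"))
    stop(path, ": role must be 'drug' or 'polymer'")
  if (!is.numeric(x$mw) || x$mw <= 0) stop(path, ": mw must be positive")
  if (!is.null(x$density) && x$density <= 0)
    stop(path, ": density must be positive")
  if (!is.null(x$gfa_class) && !x$gfa_class %in% c("I", "II", "III"))
    stop(path, ": gfa_class must be I, II or III")
  has_groups <- !is.null(x$groups)
  has_units <- !is.null(x$repeat_units)
  if (!has_groups && !has_units)
    stop(path, ": either 'groups' or 'repeat_units' is required")
  if (has_units) {
    fr <- vapply(x$repeat_units, function(u) as.numeric(u$fraction), numeric(1))
    if (any(fr < 0)) stop(path, ": repeat-unit fractions must be non-negative")
    if (abs(sum(fr) - 1) > 1e-9)
      stop(path, ": repeat-unit mole fractions must sum to 1 (got ",
           format(sum(fr)), ")")
    for (u in x$repeat_units)
      if (is.null(u$groups)) stop(path, ": each repeat unit needs 'groups'")
  }
  counts_ok <- function(gr) {
    for (m in names(gr)) {
      cnt <- unlist(gr[[m]])
      if (any(cnt < 0)) stop(path, ": negative group count under ", m)
    }
  }
  if (has_groups) counts_ok(x$groups)
  if (has_units) for (u in x$repeat_units) counts_ok(u$groups)
  invisible(x)
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s (%s, %s)\n", x$name, x$abbreviation, x$role))
  cat(sprintf("  Mw %.6g g/mol", x$mw))
  if (!is.null(x$density)) cat(sprintf(", density %.3g g/cm^3", x$density))
  if (!is.null(x$tg_c)) cat(sprintf(", Tg %.6g degC", x$tg_c))
  if (!is.null(x$tm_c)) cat(sprintf(", Tm %.6g degC", x$tm_c))
  cat("\n")
  if (!is.null(x$repeat_units))
    cat("  copolymer of", length(x$repeat_units), "repeat units\n")
  invisible(x)
}

#' Load the bundled compound library
#'
#' Reads the descriptor fixtures for the four model drugs (ibuprofen,
#' naproxen, carbamazepine, itraconazole) and seven carrier polymers
#' shipped with the package.
#'
#' @param dir Directory of YAML descriptors; defaults to the bundled set.
#' @return Named list of `compound` objects, keyed by abbreviation.
#' @export
load_compounds <- function(dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", "compounds", package = "asdscreen",
                       mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  if (length(files) == 0) stop("no compound descriptors found in ", dir)
  comps <- lapply(files, read_compound)
  names(comps) <- vapply(comps, function(x) x$abbreviation, character(1))
  comps[order(match(names(comps), c("IBU", "NAP", "CAR", "ITR",
                                    "HP50", "HAS", "PK30", "PVA",
                                    "SOL", "EUD", "EUD55")))]
}
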