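#' Group-contribution constant tables
#'
#' Reads a group-contribution table for one of the two supported estimation
#' schemes. Fedors tables carry a cohesive energy `E` (J/mol) and a molar
#' volume increment `V` (cm^3/mol) per structural group; Hoftyzer-van
#' Krevelen tables carry the dispersive and polar molar attraction constants
#' `Fd` and `Fp` ((J cm^3)^(1/2)/mol), the hydrogen-bonding cohesive energy
#' `Eh` (J/mol) and a molar volume `V`.
#'
#' @param method `"fedors"` or `"van_krevelen"`.
#' @param path Optional path to a custom tab-separated table; defaults to the
#'   bundled constants.
#' @return A `gc_table` object: a data frame keyed by group label with an
#'   attribute `method`.
#' @export
gc_table <- function(method = c("fedors", "van_krevelen"), path = NULL) {
  method <- match.arg(method)
  if (is.null(path)) {
    path <- system.file("extdata", "group_tables", paste0(method, ".tsv"),
                        package = "asdscreen", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_gc_table(tab, method)
  rownames(tab) <- tab$label
  structure(tab, method = method, class = c("gc_table", "data.frame"))
}

validate_gc_table <- function(tab, method) {
  need <- if (method == "fedors") c("label", "E", "V") else
    c("label", "Fd", "Fp", "Eh", "V")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("group table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$label))
    stop("duplicated group label(s): ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  if (method == "van_krevelen") {
    if (any(tab$Fp < 0)) stop("Fp contributions must be non-negative")
    if (any(tab$Eh < 0)) stop("Eh contributions must be non-negative")
  }
  neg_ok <- if ("neg_v" %in% names(tab)) tab$neg_v else rep(FALSE, nrow(tab))
  bad <- tab$V < 0 & !neg_ok
  if (any(bad))
    stop("negative molar volume for group(s) not flagged as branching/ring-junction: ",
         paste(tab$label[bad], collapse = ", "))
  invisible(tab)
}

#' @export
print.gc_table <- function(x, ...) {
  cat(sprintf("Group-contribution table (%s), %d groups\n",
              attr(x, "method"), nrow(x)))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

# Sum table columns over a named count vector, failing on unknown labels.
gc_sums <- function(counts, table, cols) {
  counts <- unlist(counts)
  if (length(counts) == 0 || all(counts == 0))
    stop("at least one group with a positive count is required")
  if (any(counts < 0)) stop("group counts must be non-negative")
  unknown <- setdiff(names(counts), rownames(table))
  if (length(unknown) > 0)
    stop("unknown group label(s) for the ", attr(table, "method"),
         " table: ", paste(unknown, collapse = ", "))
  vapply(cols, function(cl) sum(counts * table[names(counts), cl]), numeric(1))
}
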