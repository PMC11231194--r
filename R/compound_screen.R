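#' Default ADMET / physicochemical screening rules
#'
#' The nine drug-likeness criteria used to retain potentially active
#' compounds: the extended rule-of-five thresholds (MW <= 500 Da, nHD <= 5,
#' nHA <= 10, logP <= 5, nRot <= 10) plus oral bioavailability OB >= 30%,
#' Caco-2 permeability >= 0.4, TPSA <= 60 A^2, and no predicted
#' hepatotoxicity. All comparisons are inclusive at the boundary. Rules are
#' plain data and can be replaced or extended for other prescriptions.
#'
#' @return data.frame with columns `property`, `comparator` (`"le"`, `"ge"`,
#'   or `"eq"`) and `threshold` (for `hepatotoxic`, 0 meaning FALSE).
#' @export
default_rules <- function() {
  data.frame(
    property   = c("mw", "n_hd", "n_ha", "logp", "n_rot",
                   "ob", "caco2", "tpsa", "hepatotoxic"),
    comparator = c("le", "le", "le", "le", "le", "ge", "ge", "le", "eq"),
    threshold  = c(500, 5, 10, 5, 10, 30, 0.4, 60, 0),
    stringsAsFactors = FALSE)
}

.rule_holds <- function(x, comparator, threshold) {
  switch(comparator,
         le = x <= threshold,
         ge = x >= threshold,
         eq = as.numeric(x) == threshold,
         stop("unknown comparator: ", comparator, call. = FALSE))
}

#' Screen compounds against a rule set
#'
#' A compound passes iff every rule holds. A missing property value cannot
#' fulfil a criterion, so it fails the compound with violation
#' `"missing:<property>"`.
#'
#' @param compounds compound table as returned by [read_compound_table()] or
#'   [generate_synthetic()] (one row per compound, `herbs` list-column).
#' @param rules rule table; defaults to [default_rules()].
#' @return object of class `screen_report`: `$compounds` (per-compound `pass`
#'   flag and `violations` list-column), `$herb_counts` (passers per herb,
#'   shared compounds counted once per herb), `$n_input`, `$n_pass`, and
#'   `$n_shared` (passers belonging to two or more herbs).
#' @export
screen <- function(compounds, rules = default_rules()) {
  if (!nrow(rules)) stop("rule set is empty", call. = FALSE)
  unknown <- setdiff(rules$property, names(compounds))
  if (length(unknown)) {
    stop("screen rule refers to unknown property: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(compounds)
  violations <- rep(list(character(0)), n)
  missing_counter <- integer(0)
  for (r in seq_len(nrow(rules))) {
    prop <- rules$property[r]
    x <- compounds[[prop]]
    miss <- is.na(x)
    ok <- !miss & .rule_holds(x, rules$comparator[r], rules$threshold[r])
    for (i in which(!ok & !miss)) {
      violations[[i]] <- c(violations[[i]], prop)
    }
    for (i in which(miss)) {
      violations[[i]] <- c(violations[[i]], paste0("missing:", prop))
    }
    if (any(miss)) missing_counter[prop] <- sum(miss)
  }
  pass <- lengths(violations) == 0
  per_compound <- data.frame(compound_id = compounds$compound_id,
                             pass = pass, stringsAsFactors = FALSE)
  per_compound$violations <- I(violations)

  herbs <- compounds$herbs %||% rep(list(character(0)), n)
  pass_herbs <- unlist(herbs[pass])
  if (length(pass_herbs)) {
    tab <- table(pass_herbs)
    herb_counts <- data.frame(herb = names(tab),
                              n_pass = as.integer(tab),
                              stringsAsFactors = FALSE)
  } else {
    herb_counts <- data.frame(herb = character(0), n_pass = integer(0),
                              stringsAsFactors = FALSE)
  }

  structure(list(compounds = per_compound,
                 herb_counts = herb_counts,
                 n_input = n,
                 n_pass = sum(pass),
                 n_shared = sum(lengths(herbs[pass]) >= 2),
                 missing_by_field = missing_counter),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Compound screen: ", x$n_pass, "/", x$n_input, " compounds pass (",
      x$n_shared, " passers shared by >=2 herbs)\n", sep = "")
  if (nrow(x$herb_counts)) {
    cat("Passers per herb:\n")
    print(x$herb_counts, row.names = FALSE)
  }
  invisible(x)
}

#' Compound ids passing a screen
#' @param report a `screen_report`.
#' @return character vector of passing compound ids.
#' @export
pass_set <- function(report) {
  stopifnot(inherits(report, "screen_report"))
  report$compounds$compound_id[report$compounds$pass]
}
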