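## Lipinski / Veber / TPSA rule evaluation over a user-supplied molecular
## descriptor table. Descriptor computation (e.g. from structures) is out of
## scope; the rule engine is a pure function of the supplied numbers.

.DESCRIPTOR_FIELDS <- c("MW", "logP", "HBD", "HBA", "rotatable_bonds", "TPSA")

#' Evaluate druglikeness rules for one compound
#'
#' Counts Lipinski rule-of-five violations over
#' MW > 500 g mol\eqn{^{-1}}, logP > 5, H-bond donors > 5, H-bond
#' acceptors > 10 (a compound passes with at most one violation), and
#' evaluates Veber's rule (rotatable bonds \eqn{\le} 10 and TPSA
#' \eqn{\le} 140 \eqn{\mbox{\AA}^2}) and the TPSA permeability flag
#' (TPSA < 140 \eqn{\mbox{\AA}^2}).
#'
#' @param record Named list or one-row data frame with fields `MW`, `logP`,
#'   `HBD`, `HBA`, `rotatable_bonds`, `TPSA` (and optionally
#'   `compound_id`).
#' @return An object of class `rule_verdict`: `ro5_violations` (0--4),
#'   `ro5_pass`, `veber_pass`, `tpsa_pass`.
#' @examples
#' evaluate_rules(list(MW = 480, logP = 4.2, HBD = 2, HBA = 8,
#'                     rotatable_bonds = 7, TPSA = 120))
#' @export
evaluate_rules <- function(record) {
  record <- as.list(record)
  for (f in .DESCRIPTOR_FIELDS) {
    if (is.null(record[[f]]) || !is_number(record[[f]]))
      abort_validation(sprintf("missing or non-numeric descriptor: '%s'", f))
  }
  if (record$MW <= 0) abort_validation("'MW' must be > 0")
  if (record$HBD < 0 || record$HBA < 0 || record$rotatable_bonds < 0)
    abort_validation("counts (HBD, HBA, rotatable_bonds) must be >= 0")
  if (record$TPSA < 0) abort_validation("'TPSA' must be >= 0")
  violations <- sum(record$MW > 500, record$logP > 5,
                    record$HBD > 5, record$HBA > 10)
  structure(list(ro5_violations = violations,
                 ro5_pass = violations <= 1,
                 veber_pass = record$rotatable_bonds <= 10 && record$TPSA <= 140,
                 tpsa_pass = record$TPSA < 140),
            class = "rule_verdict")
}

#' Screen a descriptor table against druglikeness rules
#'
#' Applies [evaluate_rules()] to every row of a descriptor table and returns
#' the table augmented with the verdict columns, preserving input order.
#'
#' @param records Data frame with columns `compound_id`, `MW`, `logP`,
#'   `HBD`, `HBA`, `rotatable_bonds`, `TPSA`; compound ids must be unique.
#' @return The input data frame with added columns `ro5_violations`,
#'   `ro5_pass`, `veber_pass`, `tpsa_pass`.
#' @export
screen_table <- function(records) {
  if (!is.data.frame(records))
    abort_validation("'records' must be a data frame")
  if (!nrow(records)) {
    out <- records
    out$ro5_violations <- integer(0); out$ro5_pass <- logical(0)
    out$veber_pass <- logical(0); out$tpsa_pass <- logical(0)
    return(out)
  }
  if (!"compound_id" %in% names(records))
    abort_validation("missing or non-numeric descriptor: 'compound_id'")
  if (anyDuplicated(records$compound_id))
    abort_validation("duplicate compound_id values in descriptor table")
  verdicts <- lapply(seq_len(nrow(records)), function(i) evaluate_rules(records[i, ]))
  records$ro5_violations <- vapply(verdicts, `[[`, numeric(1), "ro5_violations")
  records$ro5_pass <- vapply(verdicts, `[[`, logical(1), "ro5_pass")
  records$veber_pass <- vapply(verdicts, `[[`, logical(1), "veber_pass")
  records$tpsa_pass <- vapply(verdicts, `[[`, logical(1), "tpsa_pass")
  records
}
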