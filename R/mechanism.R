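## Relapse-mechanism inference: does the relapse descend from the
## diagnostic leukemic clone (clonal evolution) or is it a second
## de novo leukemia arising from persistent clonal hematopoiesis?

#' Call the relapse mechanism for one patient
#'
#' Rule-based dichotomy combining loss of the founder NPM1 mutation with
#' the number of somatic mutations shared between diagnosis and relapse
#' (preleukemic/germline variants excluded from the count):
#' \itemize{
#'   \item `SECOND_DE_NOVO`: NPM1 lost at relapse and fewer than
#'     `shared_threshold` shared somatic mutations -- the original clone
#'     was cleared and a new leukemia arose on persistent clonal
#'     hematopoiesis.
#'   \item `CLONAL_EVOLUTION_RELAPSE`: NPM1 retained and at least
#'     `shared_threshold` shared somatic mutations -- a leukemic subclone
#'     survived therapy.
#'   \item `AMBIGUOUS`: any other combination, with an explanatory note.
#' }
#' The default threshold of 3 reflects the empirical separation between
#' the two patterns (persistent cases share at least three mutations,
#' loss cases almost none); it is configurable and the verdict is a pure
#' function of the evidence fields.  Remission persistence of preleukemic
#' mutations is reported as evidence only -- it supports, but is not
#' required for, either verdict.
#'
#' @param shared_somatic_count shared somatic mutations between diagnosis
#'   and relapse (see [shared_mutation_count()] with
#'   `exclude_preleukemic = TRUE`).
#' @param npm1_lost `TRUE` when the NPM1 mutation present at diagnosis is
#'   absent at relapse; must be known.
#' @param preleukemic_remission_vafs remission VAFs of
#'   preleukemic/germline variants (may be empty).
#' @param shared_threshold integer, default 3.
#' @param preleukemic_vaf_floor mean remission VAF at or above which the
#'   preleukemic clone counts as persistent (fraction, default 0.20).
#' @return list of class `mechanism_call`: `verdict`, `evidence` (fields
#'   `shared_somatic_count`, `npm1_lost`,
#'   `preleukemic_remission_persistent`), `notes`.
#' @examples
#' call_mechanism(0, npm1_lost = TRUE,
#'                preleukemic_remission_vafs = 0.36)   # SECOND_DE_NOVO
#' call_mechanism(7, npm1_lost = FALSE)                # CLONAL_EVOLUTION_RELAPSE
#' @export
call_mechanism <- function(shared_somatic_count, npm1_lost,
                           preleukemic_remission_vafs = numeric(),
                           shared_threshold = 3,
                           preleukemic_vaf_floor = 0.20) {
  if (is.na(npm1_lost)) stop("NPM1 relapse status unknown")
  stopifnot(shared_somatic_count >= 0, shared_threshold >= 0)
  persist <- length(preleukemic_remission_vafs) > 0 &&
    mean(preleukemic_remission_vafs) >= preleukemic_vaf_floor
  few_shared <- shared_somatic_count < shared_threshold
  if (npm1_lost && few_shared) {
    verdict <- "SECOND_DE_NOVO"
    notes <- "NPM1 lost with (almost) no shared somatic mutation"
  } else if (!npm1_lost && !few_shared) {
    verdict <- "CLONAL_EVOLUTION_RELAPSE"
    notes <- "NPM1 retained with a shared somatic backbone"
  } else {
    verdict <- "AMBIGUOUS"
    notes <- if (npm1_lost)
      sprintf("NPM1 lost yet %d shared somatic mutation(s) (threshold %d)",
              shared_somatic_count, shared_threshold)
    else
      sprintf("NPM1 retained yet only %d shared somatic mutation(s) (threshold %d)",
              shared_somatic_count, shared_threshold)
  }
  structure(list(verdict = verdict,
                 evidence = list(shared_somatic_count = as.integer(shared_somatic_count),
                                 npm1_lost = npm1_lost,
                                 preleukemic_remission_persistent = persist),
                 notes = notes),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("mechanism call:", x$verdict, "\n  shared somatic:",
      x$evidence$shared_somatic_count, "| NPM1 lost:",
      x$evidence$npm1_lost, "| preleukemic remission persistence:",
      x$evidence$preleukemic_remission_persistent, "\n  ", x$notes, "\n")
  invisible(x)
}

#' Call the relapse mechanism from a classified case
#'
#' Derives the evidence fields from a classified `variant_table` (shared
#' somatic count, remission VAFs of preleukemic variants) and the NPM1
#' status pair, then applies [call_mechanism()].
#'
#' @param vt a classified `variant_table` for one patient.
#' @param npm1_status_dx,npm1_status_rel `"mut"`/`"wt"` (diagnosis must
#'   be `"mut"` for the call to be meaningful; relapse must be known).
#' @param thresholds a [presence_thresholds()].
#' @param ... passed to [call_mechanism()].
#' @return a `mechanism_call`.
#' @export
call_mechanism_case <- function(vt, npm1_status_dx, npm1_status_rel,
                                thresholds = presence_thresholds(), ...) {
  if (!npm1_status_rel %in% c("mut", "wt"))
    stop("NPM1 relapse status unknown")
  shared <- shared_mutation_count(vt, exclude_preleukemic = TRUE,
                                  thresholds = thresholds)
  pre <- !is.na(vt$trajectory) & vt$trajectory == "PRELEUKEMIC_GERMLINE"
  call_mechanism(shared, npm1_lost = npm1_status_rel == "wt",
                 preleukemic_remission_vafs = vt$vaf_rem[pre], ...)
}

#' VAF trajectory matrix for one case
#'
#' One row per variant with its diagnosis, remission and relapse VAFs (as
#' fractions) and trajectory label, sorted by trajectory then gene --
#' the layout used for per-patient VAF trajectory plots.
#'
#' @param vt a classified `variant_table` for one patient.
#' @return data.frame with `gene`, `aa_change`, `vaf_dx`, `vaf_rem`,
#'   `vaf_rel`, `trajectory`.
#' @export
vaf_trajectory_matrix <- function(vt) {
  stopifnot(inherits(vt, "variant_table"))
  if (!"trajectory" %in% names(vt)) vt <- classify_trajectories(vt)
  out <- data.frame(gene = vt$gene, aa_change = vt$aa_change,
                    vaf_dx = vt$vaf_dx, vaf_rem = vt$vaf_rem,
                    vaf_rel = vt$vaf_rel, trajectory = vt$trajectory,
                    stringsAsFactors = FALSE)
  ord <- order(match(out$trajectory, TRAJECTORY_LEVELS), out$gene)
  rownames(out) <- NULL
  out[ord, , drop = FALSE]
}
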