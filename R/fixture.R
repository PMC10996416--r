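#' Confusion counts from a published trauma chest radiograph reader study
#'
#' Per-finding 2x2 counts of a reporting radiologist and a commercial
#' deep-learning reader ("ai"), each scored against the contemporaneous CT
#' report, in a cohort of 1404 blunt-trauma chest radiographs. Four
#' radiographs could not be processed by the algorithm, so the ai rows sum
#' to 1400 while the radiologist rows sum to 1404. Findings cover
#' pneumothorax, pneumomediastinum, rib/clavicle/humerus/scapula fracture
#' and lobar/segmental collapse.
#'
#' These marginal counts are sufficient to reproduce each reader's
#' sensitivity, specificity, exact binomial intervals and Cohen's kappa; they
#' do not carry per-case pairing, so paired-bootstrap comparisons cannot be
#' recomputed from them (use [simulate_dataset()] for that).
#'
#' @return A tibble with columns `finding`, `reader`, `tp`, `fp`, `tn`, `fn`.
#' @seealso [fixture_confusion()], [study_sim_config()]
#' @export
#' @examples
#' counts <- trauma_cxr_counts()
#' cohens_kappa(fixture_confusion("pneumothorax", "radiologist"))
trauma_cxr_counts <- function() {
  path <- system.file("extdata", "trauma_cxr_confusion_counts.csv",
                      package = "readeracc", mustWork = TRUE)
  readr::read_csv(path, col_types = "cciiii", progress = FALSE)
}

#' Fetch one fixture confusion table
#'
#' @param finding finding name as in [trauma_cxr_counts()].
#' @param reader `"radiologist"` or `"ai"`.
#' @return A [confusion_table].
#' @export
fixture_confusion <- function(finding, reader) {
  counts <- trauma_cxr_counts()
  row <- counts[counts$finding == finding & counts$reader == reader, ]
  if (nrow(row) != 1) {
    stop("no fixture entry for finding '", finding, "', reader '", reader,
         "'", call. = FALSE)
  }
  confusion_table(tp = row$tp, fp = row$fp, fn = row$fn, tn = row$tn)
}
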