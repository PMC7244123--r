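## Rule-based classification of a receptor's per-branch indexes into the three
## evolutionary scenarios: pre-existing conserved pocket (S1), progressive
## pocket acquisition (S2), pocket reshuffling at ligand appearance (S3).

#' Classifier thresholds
#'
#' @param omegaPositive Omega above which a branch counts as positively
#'   selected (default 1).
#' @param omegaLow Omega below which a branch counts as purifying (default 1).
#' @param pocketIdLowMax Maximum pocket identity (%) for "pocket absent"
#'   pre-ligand branches (default 30).
#' @param pocketIdHighMin Minimum pocket identity (%) required in every branch
#'   for a pre-existing pocket (default 40).
#' @param nLowMax Maximum within-branch non-synonymous count regarded as low
#'   (default 20).
#' @param alpha Significance level for the identity comparison (default 0.05).
#' @param nContrastAlpha Level for the pre- vs post-ligand N contrast
#'   (default 0.05).
#' @param monotoneSlack Allowed per-step decrease (percentage points) when
#'   testing that pocket identity increases across ligand-present branches;
#'   default 12, about 1.5 standard errors of the difference between two
#'   few-species 25-residue identity estimates.
#' @param terminalIdMin Minimum terminal (mammal) pocket identity for the
#'   reshuffling scenario (default 90).
#' @return Named list of thresholds.
#' @export
scenarioThresholds <- function(omegaPositive = 1, omegaLow = 1,
                               pocketIdLowMax = 30, pocketIdHighMin = 40,
                               nLowMax = 20, alpha = 0.05,
                               nContrastAlpha = 0.05, monotoneSlack = 12,
                               terminalIdMin = 90) {
  stopifnot(pocketIdLowMax < pocketIdHighMin)
  list(omegaPositive = omegaPositive, omegaLow = omegaLow,
       pocketIdLowMax = pocketIdLowMax, pocketIdHighMin = pocketIdHighMin,
       nLowMax = nLowMax, alpha = alpha, nContrastAlpha = nContrastAlpha,
       monotoneSlack = monotoneSlack, terminalIdMin = terminalIdMin)
}

## non-strict monotone increase with a small slack per step
.increasing <- function(x, slack) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(TRUE)
  all(diff(x) >= -slack)
}

.fmt <- function(x, digits = 3) {
  if (is.numeric(x)) paste(format(round(x, digits), trim = TRUE), collapse = ",")
  else paste(x, collapse = ",")
}

#' Classify a receptor's index table into an evolutionary scenario
#'
#' Evaluates the mandatory criteria of the three scenarios in order S1, S2,
#' S3; the first fully satisfied scenario wins, otherwise the call is
#' UNCLASSIFIED. An undefined (NA) omega satisfies neither an "omega above"
#' nor an "omega below" criterion. Every criterion outcome is reported in the
#' evidence trail so borderline cases are auditable.
#'
#' Mandatory criteria (th = thresholds):
#' * S1: omega < omegaLow in every branch; pocket identity >= pocketIdHighMin
#'   in every branch; pocket significantly higher than whole-sequence identity
#'   in every branch; N <= nLowMax in every branch; no positively selected
#'   pocket site.
#' * S2: pocket identity <= pocketIdLowMax in every pre-ligand branch;
#'   identity increasing across ligand-present branches; omega > omegaPositive
#'   in at least one ligand-present branch; pocket never significantly higher
#'   than the whole sequence; N <= nLowMax in every branch; no positively
#'   selected pocket site.
#' * S3: pocket identity <= pocketIdLowMax in every pre-ligand branch;
#'   identity increasing across ligand-present branches with terminal value
#'   >= terminalIdMin; omega < omegaLow in the branches after ligand
#'   appearance; omega > omegaPositive in the appearance branch; N
#'   significantly higher pre-ligand than ligand-present (one-sided Welch
#'   test); no positively selected pocket site. (Pre-ligand omega above 1 is
#'   common in this scenario but not mandatory.)
#'
#' @param x An [IndexTable-class].
#' @param thresholds A list from [scenarioThresholds].
#' @return A [ScenarioCall-class].
#' @export
classifyScenario <- function(x, thresholds = scenarioThresholds()) {
  stopifnot(methods::is(x, "IndexTable"))
  th <- thresholds
  tb <- indexTable(x)
  usable <- tb$n_species > 0
  pre <- usable & !tb$ligand_present
  post <- usable & tb$ligand_present
  appearance <- tb$group == x@ligandGroup
  if (sum(pre) < 2 || sum(post) < 1) {
    return(methods::new("ScenarioCall", label = "UNCLASSIFIED",
      criteria = data.frame(criterion = character(0), satisfied = logical(0),
                            detail = character(0)),
      notes = sprintf(paste0("need >= 2 pre-ligand and >= 1 ligand-present ",
                             "branches with species (have %d and %d)"),
                      sum(pre), sum(post))))
  }
  om <- tb$omega_pocket
  pid <- tb$pct_id_pocket
  nn <- tb$n_nonsyn_pocket
  sig <- !is.na(tb$p_pocket_vs_whole) & tb$p_pocket_vs_whole < th$alpha
  pocketHigher <- sig & tb$direction == "pocket-higher"
  posPocket <- positiveSitesInPocket(
    data.frame(column = x@positiveSites,
               class = rep("positive", length(x@positiveSites))),
    x@pocketColumns)
  postAfter <- post & !appearance  # branches after the appearance branch
  ## N contrast: pre-ligand vs ligand-present, one-sided
  nPre <- nn[pre & !is.na(nn)]
  nPost <- nn[post & !is.na(nn)]
  nContrastP <- if (length(nPre) >= 2 && length(nPost) >= 2 &&
                    (stats::sd(nPre) > 0 || stats::sd(nPost) > 0)) {
    stats::t.test(nPre, nPost, alternative = "greater")$p.value
  } else if (length(nPre) >= 2 && length(nPost) >= 2) {
    if (mean(nPre) > mean(nPost)) 0 else 1
  } else NA_real_
  crit <- list()
  add <- function(id, ok, detail)
    crit[[length(crit) + 1]] <<- data.frame(criterion = id, satisfied = ok,
                                            detail = detail,
                                            stringsAsFactors = FALSE)
  ## --- S1 ---
  add("S1a_omega_low_everywhere",
      all(!is.na(om[usable]) & om[usable] < th$omegaLow),
      paste0("omega=", .fmt(om[usable])))
  add("S1b_pocket_id_high_everywhere",
      all(!is.na(pid[usable]) & pid[usable] >= th$pocketIdHighMin),
      paste0("pct_id_pocket=", .fmt(pid[usable], 1)))
  add("S1c_pocket_higher_everywhere", all(pocketHigher[usable]),
      paste0("direction=", .fmt(tb$direction[usable]), " p=",
             .fmt(tb$p_pocket_vs_whole[usable])))
  add("S1d_n_low_everywhere",
      all(!is.na(nn[usable]) & nn[usable] <= th$nLowMax),
      paste0("N=", .fmt(nn[usable], 0)))
  add("S1e_no_positive_pocket_sites", !posPocket$any,
      paste0("positive pocket sites: ", .fmt(posPocket$sites, 0)))
  ## --- S2 ---
  add("S2a_pocket_id_low_preligand",
      all(!is.na(pid[pre]) & pid[pre] <= th$pocketIdLowMax),
      paste0("pre pct_id_pocket=", .fmt(pid[pre], 1)))
  add("S2b_pocket_id_increasing_postligand",
      .increasing(pid[post], th$monotoneSlack),
      paste0("post pct_id_pocket=", .fmt(pid[post], 1)))
  add("S2c_omega_positive_some_postligand",
      any(!is.na(om[post]) & om[post] > th$omegaPositive),
      paste0("post omega=", .fmt(om[post])))
  add("S2d_pocket_never_higher", all(!pocketHigher[usable]),
      paste0("direction=", .fmt(tb$direction[usable])))
  add("S2e_n_low_everywhere",
      all(!is.na(nn[usable]) & nn[usable] <= th$nLowMax),
      paste0("N=", .fmt(nn[usable], 0)))
  add("S2f_no_positive_pocket_sites", !posPocket$any,
      paste0("positive pocket sites: ", .fmt(posPocket$sites, 0)))
  ## --- S3 ---
  add("S3a_pocket_id_low_preligand",
      all(!is.na(pid[pre]) & pid[pre] <= th$pocketIdLowMax),
      paste0("pre pct_id_pocket=", .fmt(pid[pre], 1)))
  termId <- pid[usable][sum(usable)]
  add("S3b_pocket_id_increasing_to_high_terminal",
      .increasing(pid[post], th$monotoneSlack) &&
        !is.na(termId) && termId >= th$terminalIdMin,
      paste0("post pct_id_pocket=", .fmt(pid[post], 1),
             " terminal=", .fmt(termId, 1)))
  add("S3c_omega_low_after_appearance",
      all(!is.na(om[postAfter]) & om[postAfter] < th$omegaLow),
      paste0("post-appearance omega=", .fmt(om[postAfter])))
  omApp <- om[appearance & usable]
  add("S3d_omega_positive_at_appearance",
      length(omApp) > 0 && all(!is.na(omApp) & omApp > th$omegaPositive),
      paste0("appearance omega=", .fmt(omApp)))
  add("S3e_n_higher_preligand",
      !is.na(nContrastP) && nContrastP < th$nContrastAlpha,
      paste0("N pre=", .fmt(nn[pre], 0), " post=", .fmt(nn[post], 0),
             " p=", .fmt(nContrastP)))
  add("S3f_no_positive_pocket_sites", !posPocket$any,
      paste0("positive pocket sites: ", .fmt(posPocket$sites, 0)))
  criteria <- do.call(rbind, crit)
  ok <- function(prefix) all(criteria$satisfied[startsWith(criteria$criterion, prefix)])
  label <- if (ok("S1")) "S1" else if (ok("S2")) "S2" else if (ok("S3")) "S3"
           else "UNCLASSIFIED"
  methods::new("ScenarioCall", label = label, criteria = criteria, notes = "")
}
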