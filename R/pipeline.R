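## End-to-end duo analysis and cohort pipeline orchestration.

#' Analyse one mole/mother duo
#'
#' Runs the full caller chain on a duo: per-autosome copy-number calls and
#' sex constitution ([estimate_karyotype()]), selected-BAF origin calls on
#' every unambiguous autosome ([call_origin()]), and optionally the STR
#' classification. A supernumerary Y (or X) chromosome is annotated as
#' paternal by constitution: in an androgenetic conceptus all sex
#' chromosomes come from sperm, and a Y can never be maternal.
#'
#' @param mole,mother \code{snp_sample} tables of the duo.
#' @param panel the [locus_panel()] the duo was typed on.
#' @param mole_str,mother_str optional \code{str_profile} objects.
#' @param id case identifier (defaults to the mole sample ID).
#' @param outcome optional post-molar outcome label (\code{"SR"} /
#'   \code{"GTN"}).
#' @param loss_threshold,top_band_cut,min_selected origin-caller
#'   thresholds, see [call_origin()].
#' @param ... further arguments for [call_copy_number()] via
#'   [estimate_karyotype()].
#' @return A per-case call list with fields \code{id}, \code{karyotype},
#'   \code{str_class}, \code{origin_calls}, \code{extra_origins} (named
#'   vector chromosome -> origin), \code{biparental_disomies},
#'   \code{aneuploid}, \code{maternal_contribution} and \code{outcome}.
#' @export
analyze_duo <- function(mole, mother, panel, mole_str = NULL,
                        mother_str = NULL, id = NULL,
                        outcome = NA_character_,
                        loss_threshold = 0.25, top_band_cut = 0.85,
                        min_selected = 30L, ...) {
  if (is.null(id)) id <- mole$sample_id[1]
  kary <- estimate_karyotype(mole, ...)
  selected <- select_loci_maternal_AA(mole, mother)
  origin_calls <- list()
  extra_origins <- character()
  biparental <- character()
  for (chrom in names(kary$calls)) {
    cc <- kary$calls[[chrom]]
    if (cc$ambiguous) next
    oc <- call_origin(mole, mother, cc, panel,
                      loss_threshold = loss_threshold,
                      top_band_cut = top_band_cut,
                      min_selected = min_selected, selected = selected)
    origin_calls[[chrom]] <- oc
    if (cc$copy_number >= 3 && oc$extra_origin != "undetermined")
      extra_origins[[chrom]] <- oc$extra_origin
    if (isTRUE(oc$biparental_disomy))
      biparental <- c(biparental, chrom)
  }
  # supernumerary sex chromosomes are paternal by constitution
  sex_letters <- strsplit(kary$sex, "")[[1]]
  n_x <- sum(sex_letters == "X")
  n_y <- sum(sex_letters == "Y")
  base_x <- if (n_y > 0) 1L else 2L
  if (n_x > base_x) extra_origins[["X"]] <- "paternal"
  if (n_y > 1) extra_origins[["Y"]] <- "paternal"
  aneuploid <- kary$sex %in% c("XX", "XY") == FALSE ||
    length(kary$gains) > 0 || length(kary$losses) > 0
  maternal_contribution <- any(extra_origins == "maternal") ||
    length(biparental) > 0
  list(
    id = id,
    karyotype = kary,
    str_class = if (!is.null(mole_str) && !is.null(mother_str))
      classify_conceptus(mole_str, mother_str) else NULL,
    origin_calls = origin_calls,
    extra_origins = extra_origins,
    biparental_disomies = biparental,
    aneuploid = aneuploid,
    maternal_contribution = maternal_contribution,
    outcome = outcome
  )
}

#' Run the simulate-classify-karyotype-origin-report pipeline
#'
#' Orchestrates the full chain on a simulated cohort: generates duos from
#' a cohort constitution table, writes the rendered final-report and STR
#' tables, analyses every duo, and writes per-case JSON calls plus a
#' cohort report (TSV and JSON). All outputs are written atomically and
#' the whole run is reproducible from the root seed.
#'
#' @param config list (or path to a YAML file) with elements
#'   \code{cohort_spec} (data frame, list of specs, or path to a CSV such
#'   as the shipped [chm31_cohort()] table), \code{seed} (required
#'   integer), \code{out_dir} (required), and optionally \code{noise}
#'   (list of [noise_model()] arguments) and \code{thresholds} (list of
#'   [analyze_duo()] threshold arguments).
#' @param panel the [locus_panel()] to simulate on.
#' @param quiet suppress progress messages.
#' @return List with \code{report} (a \code{cohort_report}),
#'   \code{stratification}, \code{cases} (per-case call lists) and
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config, panel = default_locus_panel(),
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config error: 'seed' is required")
  if (is.null(config$out_dir)) stop("config error: 'out_dir' is required")
  spec <- config$cohort_spec
  if (is.character(spec))
    spec <- utils::read.csv(spec, stringsAsFactors = FALSE,
                            colClasses = "character")
  noise <- do.call(noise_model, as.list(config$noise))
  thresholds <- as.list(config$thresholds)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  say("simulate: generating cohort (seed ", config$seed, ")")
  cohort <- simulate_cohort(spec, panel = panel, noise = noise,
                            seed = config$seed)
  say("simulate: ", length(cohort), " duos rendered")

  out <- file.path(config$out_dir)
  write_final_report(
    unlist(lapply(cohort, function(cs) list(cs$mole, cs$mother)),
           recursive = FALSE),
    file.path(out, "cohort_final_report.tsv"))
  write_str_table(
    unlist(lapply(cohort, function(cs) list(cs$mole_str, cs$mother_str)),
           recursive = FALSE),
    file.path(out, "cohort_str.csv"))

  cases <- lapply(cohort, function(cs) {
    call <- do.call(analyze_duo, c(list(
      mole = cs$mole, mother = cs$mother, panel = panel,
      mole_str = cs$mole_str, mother_str = cs$mother_str,
      id = cs$id, outcome = cs$outcome), thresholds))
    .write_atomic(function(p) jsonlite::write_json(
      list(id = call$id,
           karyotype = call$karyotype$string,
           confident = call$karyotype$confident,
           str_class = if (!is.null(call$str_class))
             call$str_class$category else NULL,
           extra_origins = as.list(call$extra_origins),
           biparental_disomies = call$biparental_disomies,
           aneuploid = call$aneuploid,
           maternal_contribution = call$maternal_contribution,
           outcome = call$outcome),
      p, auto_unbox = TRUE, null = "null", na = "null"),
      file.path(out, paste0(cs$id, "_call.json")))
    say("analyze: ", cs$id, " -> ", call$karyotype$string)
    call
  })

  report <- summarize_cohort(cases)
  strat <- gtn_stratification(report)
  .write_atomic(function(p)
    utils::write.table(report$cases, p, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    file.path(out, "cohort_report.tsv"))
  .write_atomic(function(p) jsonlite::write_json(
    list(n_cases = report$n_cases, n_euploid = report$n_euploid,
         n_aneuploid = report$n_aneuploid,
         n_maternal_extras = report$n_maternal_extras,
         n_paternal_extras = report$n_paternal_extras,
         n_biparental_disomies = report$n_biparental_disomies,
         gtn = report$gtn,
         stratification = strat),
    p, auto_unbox = TRUE, dataframe = "rows"),
    file.path(out, "cohort_report.json"))
  say("report: ", report$n_aneuploid, "/", report$n_cases,
      " cases aneuploid")
  list(report = report, stratification = strat, cases = cases,
       out_dir = out)
}
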