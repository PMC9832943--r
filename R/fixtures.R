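# Deterministic synthetic design files with ground-truth manifests.
# These emulate the design-software output the planner consumes: declared
# per-reaction annealing optima and product lengths, random base filler
# for oligo sequences. They make every parser and planner test
# self-contained and reproducible.

#' Specification for a synthetic combinatorial design
#'
#' @param n_assemblies number of constructs (>= 1).
#' @param fragments_per_assembly pieces per construct (>= 2).
#' @param ta_range low/high annealing optimum in degC (within 50-75).
#' @param length_range min/max product length in bp (within 100-10000).
#' @param delta_policy `"all_default"` leaves the per-reaction delta blank
#'   (the planner then applies its default 0.4 degC tolerance);
#'   `"mixed"` gives half the reactions a rigid 0.2 degC delta and half a
#'   permissive 1.0 degC delta.
#' @param seed integer seed; the same spec always yields a byte-identical
#'   file.
#' @param strategy assembly strategy recorded in the manifest.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_assemblies = 4, fragments_per_assembly = 4,
                         ta_range = c(58, 66), length_range = c(500, 4000),
                         delta_policy = c("all_default", "mixed"),
                         seed = 1L,
                         strategy = c("golden_gate", "pcr_only",
                                      "iva_onepot", "aqua")) {
  delta_policy <- match.arg(delta_policy)
  strategy <- match.arg(strategy)
  stopifnot(
    n_assemblies >= 1, fragments_per_assembly >= 2,
    ta_range[1] >= 50, ta_range[2] <= 75, ta_range[1] <= ta_range[2],
    length_range[1] >= 100, length_range[2] <= 10000,
    length_range[1] <= length_range[2]
  )
  structure(
    list(n_assemblies = as.integer(n_assemblies),
         fragments_per_assembly = as.integer(fragments_per_assembly),
         ta_range = as.numeric(ta_range),
         length_range = as.integer(length_range),
         delta_policy = delta_policy, seed = as.integer(seed),
         strategy = strategy),
    class = "fixture_spec"
  )
}

random_bases <- function(n, len = 30) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic combinatorial design file
#'
#' Writes a parseable four-section design file plus a JSON manifest
#' recording every generated value (names, annealing optima, deltas,
#' lengths, piece order per construct), which serves as the ground truth
#' oracle for parser tests. Each construct gets its own set of PCR
#' reactions; each reaction has a distinct forward primer, reverse primer
#' and template, so the design uses `3 * n_assemblies *
#' fragments_per_assembly` distinct primers+templates. Annealing optima
#' are drawn uniformly on `ta_range` and rounded to 0.1 degC; product
#' lengths are uniform integers on `length_range`.
#'
#' @param spec a [fixture_spec()].
#' @param dir directory to write into (created if absent).
#' @return list with `path` (design file), `manifest_path`, and
#'   `manifest` (the parsed manifest).
#' @export
#' @examples
#' fx <- generate_design(fixture_spec(n_assemblies = 2, seed = 7),
#'                       dir = tempfile())
#' fx$manifest$n_pcrs
generate_design <- function(spec, dir = tempfile("design")) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_pcr <- spec$n_assemblies * spec$fragments_per_assembly
  n_items <- 3L * n_pcr  # fwd + rev primer + template per reaction
  if (n_items > 96) {
    stop_buildplanr(
      "buildplanr_fixture_error",
      sprintf("design would need %d primers+templates, above the 96 capacity",
              n_items)
    )
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  ta <- round_tenth(stats::runif(n_pcr, spec$ta_range[1], spec$ta_range[2]))
  len <- sample(seq(spec$length_range[1], spec$length_range[2]), n_pcr,
                replace = TRUE)
  delta <- switch(spec$delta_policy,
    all_default = rep(NA_real_, n_pcr),
    mixed = rep(c(0.2, 1.0), length.out = n_pcr)
  )

  oligos <- tibble::tibble(
    name = paste0("oligo_", seq_len(2L * n_pcr)),
    sequence = random_bases(2L * n_pcr),
    # primer pair Tm values straddle the reaction optimum symmetrically
    anneal_tm = as.vector(rbind(ta - 0.3, ta + 0.3)),
    cost = round(stats::runif(2L * n_pcr, 2, 12), 2)
  )
  pcrs <- tibble::tibble(
    id = seq_len(n_pcr),
    template_name = paste0("template_", seq_len(n_pcr)),
    fwd_oligo = paste0("oligo_", 2L * seq_len(n_pcr) - 1L),
    rev_oligo = paste0("oligo_", 2L * seq_len(n_pcr)),
    product_length = len,
    ta_opt = ta,
    delta = delta,
    note = paste0("frag_", seq_len(n_pcr))
  )
  kind <- if (spec$strategy == "golden_gate") "golden_gate" else "homology"
  pieces <- tibble::tibble(
    id = seq_len(n_pcr), source_pcr = seq_len(n_pcr),
    length = len, piece_kind = kind
  )
  combos <- tibble::tibble(
    construct_name = paste0("construct_", seq_len(spec$n_assemblies)),
    piece_ids = purrr::map(seq_len(spec$n_assemblies), function(a) {
      seq.int((a - 1L) * spec$fragments_per_assembly + 1L,
              a * spec$fragments_per_assembly)
    })
  )

  bundle <- design_bundle(oligos, pcrs, pieces, combos,
                          strategy = spec$strategy)
  path <- file.path(dir, sprintf("design_seed%d.csv", spec$seed))
  write_design(bundle, path)

  manifest <- list(
    spec = unclass(spec),
    n_pcrs = n_pcr,
    oligos = as.list(oligos[c("name", "anneal_tm")]),
    pcrs = as.list(pcrs[c("id", "template_name", "fwd_oligo", "rev_oligo",
                          "product_length", "ta_opt", "delta")]),
    piece_order = purrr::map(combos$piece_ids, identity),
    construct_names = combos$construct_name
  )
  manifest_path <- file.path(dir, sprintf("manifest_seed%d.json", spec$seed))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", na = "null")
  list(path = path, manifest_path = manifest_path, manifest = manifest)
}

# save/restore the global RNG state so fixture generation is pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Four-construct chromoprotein-style fixture with shared backbone pieces
#'
#' Builds the canonical benchmark design: four expression-vector
#' constructs, each assembled from four pieces, amplified by seven
#' distinct PCR reactions. Three reactions (pieces 2, 5 and 6) are
#' backbone/selection parts shared by every construct; four reactions
#' (pieces 1, 3, 4 and 7) are construct-specific reporter parts. Each
#' construct therefore uses its own reporter piece plus the three shared
#' backbone pieces.
#'
#' @param dir directory to write into.
#' @param strategy `"golden_gate"` (default) or `"aqua"`.
#' @param seed seed for the sequence filler and length draw.
#' @return as [generate_design()].
#' @export
chromoprotein_like_fixture <- function(dir = tempfile("chromo"),
                                       strategy = c("golden_gate", "aqua"),
                                       seed = 42L) {
  strategy <- match.arg(strategy)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_pcr <- 7L
  reporter <- c(1L, 3L, 4L, 7L)   # construct-specific chromoprotein parts
  backbone <- c(2L, 5L, 6L)       # shared backbone + selection parts
  ta <- round_tenth(stats::runif(n_pcr, 59, 65))
  len <- c(720L, 2450L, 705L, 690L, 1210L, 980L, 735L)

  oligos <- tibble::tibble(
    name = paste0("oligo_", seq_len(2L * n_pcr)),
    sequence = random_bases(2L * n_pcr),
    anneal_tm = as.vector(rbind(ta - 0.3, ta + 0.3)),
    cost = round(stats::runif(2L * n_pcr, 2, 12), 2)
  )
  pcrs <- tibble::tibble(
    id = seq_len(n_pcr),
    template_name = paste0("template_", seq_len(n_pcr)),
    fwd_oligo = paste0("oligo_", 2L * seq_len(n_pcr) - 1L),
    rev_oligo = paste0("oligo_", 2L * seq_len(n_pcr)),
    product_length = len,
    ta_opt = ta,
    delta = NA_real_,
    note = c("reporter_1", "backbone_a", "reporter_2", "reporter_3",
             "backbone_b", "selection", "reporter_4")
  )
  kind <- if (strategy == "golden_gate") "golden_gate" else "homology"
  pieces <- tibble::tibble(
    id = seq_len(n_pcr), source_pcr = seq_len(n_pcr),
    length = len, piece_kind = kind
  )
  combos <- tibble::tibble(
    construct_name = paste0("construct_", seq_len(4L)),
    piece_ids = purrr::map(reporter, ~ c(.x, backbone))
  )

  bundle <- design_bundle(oligos, pcrs, pieces, combos, strategy = strategy)
  path <- file.path(dir, "chromoprotein_like_design.csv")
  write_design(bundle, path)
  manifest <- list(
    seed = seed, strategy = strategy, n_pcrs = n_pcr,
    backbone_pieces = backbone, reporter_pieces = reporter,
    lengths = len, ta_opt = ta,
    piece_order = purrr::map(combos$piece_ids, identity),
    construct_names = combos$construct_name
  )
  manifest_path <- file.path(dir, "chromoprotein_like_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  list(path = path, manifest_path = manifest_path, manifest = manifest)
}
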