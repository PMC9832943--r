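# Data model for combinatorial assembly designs: oligos, PCR reactions,
# assembly pieces, and piece combinations, as split out of a j5-style
# combinatorial design file.

SECTION_TOKENS <- c(
  oligos = "Oligo Synthesis",
  pcrs = "PCR Reactions",
  pieces = "Assembly Pieces",
  combinations = "Combinations of Assembly Pieces"
)

OLIGO_COLS <- c("Name", "Sequence", "Anneal Tm (C)", "Cost")
PCR_COLS <- c(
  "ID", "Template", "Forward Oligo", "Reverse Oligo",
  "Product Length (bp)", "Mean Anneal Tm (C)", "Delta (C)", "Note"
)
PIECE_COLS <- c("ID", "Source PCR", "Length (bp)", "Kind")
COMBO_COLS <- c("Construct", "Piece IDs")

STRATEGIES <- c("pcr_only", "golden_gate", "iva_onepot", "aqua")

#' Construct a design bundle
#'
#' A design bundle is the in-memory form of a combinatorial assembly
#' design: four tibbles (oligos, PCR reactions, assembly pieces, piece
#' combinations) plus the chosen assembly strategy. Identifiers are
#' trimmed of surrounding whitespace and matched case-sensitively. A
#' missing per-reaction mean annealing temperature is filled in as the
#' arithmetic mean of the two primers' annealing temperatures.
#'
#' The constructor checks shape and resolvability of the piece -> PCR and
#' PCR -> oligo/template references (raising a classed reference error on
#' failure); soft design-rule violations such as the 96 primer+template
#' capacity are reported, not thrown, by [validate_design()].
#'
#' @param oligos tibble with columns `name`, `sequence`, `anneal_tm`,
#'   `cost` (cost may be `NA`).
#' @param pcrs tibble with columns `id`, `template_name`, `fwd_oligo`,
#'   `rev_oligo`, `product_length`, `ta_opt`, `delta`, `note`
#'   (`ta_opt`/`delta`/`note` may be `NA`).
#' @param pieces tibble with columns `id`, `source_pcr`, `length`,
#'   `piece_kind` (`"golden_gate"` or `"homology"`).
#' @param combinations tibble with columns `construct_name` and
#'   `piece_ids` (a list-column of integer vectors, order preserved).
#' @param strategy one of `"pcr_only"`, `"golden_gate"`, `"iva_onepot"`,
#'   `"aqua"`.
#' @param check_refs if `FALSE`, skip cross-reference resolution (used
#'   internally to build deliberately broken bundles for validation tests).
#' @return an object of class `design_bundle`.
#' @seealso [parse_design()], [validate_design()], [write_section_tables()]
#' @export
design_bundle <- function(oligos, pcrs, pieces, combinations,
                          strategy = c("pcr_only", "golden_gate",
                                       "iva_onepot", "aqua"),
                          check_refs = TRUE) {
  strategy <- match.arg(strategy)
  oligos <- tibble::as_tibble(oligos)
  pcrs <- tibble::as_tibble(pcrs)
  pieces <- tibble::as_tibble(pieces)
  combinations <- tibble::as_tibble(combinations)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop_buildplanr(
        "buildplanr_schema_error",
        sprintf("%s table lacks column(s): %s", what,
                paste(miss, collapse = ", "))
      )
    }
  }
  need(oligos, c("name", "sequence", "anneal_tm"), "oligos")
  need(pcrs, c("id", "template_name", "fwd_oligo", "rev_oligo",
               "product_length"), "pcrs")
  need(pieces, c("id", "source_pcr", "length", "piece_kind"), "pieces")
  need(combinations, c("construct_name", "piece_ids"), "combinations")

  if (!"cost" %in% names(oligos)) oligos$cost <- NA_real_
  if (!"ta_opt" %in% names(pcrs)) pcrs$ta_opt <- NA_real_
  if (!"delta" %in% names(pcrs)) pcrs$delta <- NA_real_
  if (!"note" %in% names(pcrs)) pcrs$note <- NA_character_

  oligos <- dplyr::mutate(
    oligos,
    name = stringr::str_trim(.data$name),
    sequence = toupper(stringr::str_trim(.data$sequence)),
    anneal_tm = as.numeric(.data$anneal_tm),
    cost = as.numeric(.data$cost)
  )
  pcrs <- dplyr::mutate(
    pcrs,
    id = as.integer(.data$id),
    template_name = stringr::str_trim(.data$template_name),
    fwd_oligo = stringr::str_trim(.data$fwd_oligo),
    rev_oligo = stringr::str_trim(.data$rev_oligo),
    product_length = as.integer(.data$product_length),
    ta_opt = as.numeric(.data$ta_opt),
    delta = as.numeric(.data$delta),
    note = as.character(.data$note)
  )
  pieces <- dplyr::mutate(
    pieces,
    id = as.integer(.data$id),
    source_pcr = as.integer(.data$source_pcr),
    length = as.integer(.data$length),
    piece_kind = as.character(.data$piece_kind)
  )
  combinations <- dplyr::mutate(
    combinations,
    construct_name = stringr::str_trim(.data$construct_name),
    piece_ids = purrr::map(.data$piece_ids, as.integer)
  )

  if (check_refs) {
    tm <- stats::setNames(oligos$anneal_tm, oligos$name)
    for (i in seq_len(nrow(pcrs))) {
      for (ref in c(pcrs$fwd_oligo[i], pcrs$rev_oligo[i])) {
        if (!ref %in% oligos$name) reference_error(ref)
      }
    }
    bad_piece <- !pieces$source_pcr %in% pcrs$id
    if (any(bad_piece)) {
      reference_error(sprintf("piece %d -> PCR %d",
                              pieces$id[which(bad_piece)[1]],
                              pieces$source_pcr[which(bad_piece)[1]]))
    }
    for (i in seq_len(nrow(combinations))) {
      missing_id <- setdiff(combinations$piece_ids[[i]], pieces$id)
      if (length(missing_id) > 0) {
        reference_error(sprintf("combination %s -> piece %d",
                                combinations$construct_name[i],
                                missing_id[1]))
      }
    }
    # fill missing mean annealing optima from the two primers
    fill <- is.na(pcrs$ta_opt)
    if (any(fill)) {
      pcrs$ta_opt[fill] <- (tm[pcrs$fwd_oligo[fill]] +
                              tm[pcrs$rev_oligo[fill]]) / 2
    }
  }

  structure(
    list(oligos = oligos, pcrs = pcrs, pieces = pieces,
         combinations = combinations, strategy = strategy),
    class = "design_bundle"
  )
}

#' @export
print.design_bundle <- function(x, ...) {
  cat(sprintf(
    "<design_bundle> strategy: %s\n  %d oligos, %d PCR reactions, %d pieces, %d combinations\n",
    x$strategy, nrow(x$oligos), nrow(x$pcrs), nrow(x$pieces),
    nrow(x$combinations)
  ))
  cat(sprintf("  distinct primers + templates: %d (capacity 96)\n",
              design_capacity(x)))
  invisible(x)
}

# combined count of distinct primers and distinct templates
design_capacity <- function(bundle) {
  length(unique(c(bundle$pcrs$fwd_oligo, bundle$pcrs$rev_oligo))) +
    length(unique(bundle$pcrs$template_name))
}

read_section_lines <- function(lines, token) {
  hdr <- which(stringr::str_trim(lines) == token)
  if (length(hdr) == 0) parse_error(token, sprintf("missing section: %s", token))
  start <- hdr[1] + 1
  other <- which(stringr::str_trim(lines) %in% SECTION_TOKENS)
  following <- other[other > hdr[1]]
  end <- if (length(following) > 0) following[1] - 1 else length(lines)
  body <- lines[start:min(end, length(lines))]
  body <- body[stringr::str_trim(body) != ""]
  if (length(body) < 1) parse_error(token, sprintf("section has no header row: %s", token))
  if (!grepl(",", body[1]) || grepl(";", body[1])) {
    parse_error(token, sprintf(
      "section %s: column header must be comma-delimited", token))
  }
  if (length(body) < 2) parse_error(token)
  readr::read_csv(I(paste(body, collapse = "\n")),
                  col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

#' Parse a combinatorial design file
#'
#' Reads a single UTF-8, comma-delimited design file containing the four
#' named sections `"Oligo Synthesis"`, `"PCR Reactions"`,
#' `"Assembly Pieces"` and `"Combinations of Assembly Pieces"` (each a
#' section-header line, a column-header row, then data rows) and returns
#' the corresponding [design_bundle()] with rows in file order.
#'
#' @param file path to the design file.
#' @param strategy assembly strategy recorded on the bundle.
#' @return a `design_bundle`.
#' @export
#' @examples
#' fx <- generate_design(fixture_spec(n_assemblies = 2, seed = 1),
#'                       dir = tempfile())
#' bundle <- parse_design(fx$path, strategy = "golden_gate")
#' bundle
parse_design <- function(file, strategy = c("pcr_only", "golden_gate",
                                            "iva_onepot", "aqua")) {
  strategy <- match.arg(strategy)
  if (!file.exists(file)) {
    stop_buildplanr("buildplanr_io_error",
                    sprintf("design file not found: %s", file))
  }
  lines <- readr::read_lines(file)

  oligo_raw <- read_section_lines(lines, SECTION_TOKENS[["oligos"]])
  pcr_raw <- read_section_lines(lines, SECTION_TOKENS[["pcrs"]])
  piece_raw <- read_section_lines(lines, SECTION_TOKENS[["pieces"]])
  combo_raw <- read_section_lines(lines, SECTION_TOKENS[["combinations"]])

  check_cols <- function(df, cols, token) {
    if (!all(cols %in% names(df))) parse_error(token, sprintf(
      "section %s: expected columns %s", token, paste(cols, collapse = ", ")))
  }
  check_cols(oligo_raw, OLIGO_COLS[1:3], SECTION_TOKENS[["oligos"]])
  check_cols(pcr_raw, PCR_COLS[1:5], SECTION_TOKENS[["pcrs"]])
  check_cols(piece_raw, PIECE_COLS, SECTION_TOKENS[["pieces"]])
  check_cols(combo_raw, COMBO_COLS, SECTION_TOKENS[["combinations"]])

  design_bundle(
    oligos = tibble::tibble(
      name = oligo_raw[["Name"]],
      sequence = oligo_raw[["Sequence"]],
      anneal_tm = as.numeric(oligo_raw[["Anneal Tm (C)"]]),
      cost = if ("Cost" %in% names(oligo_raw))
        as.numeric(oligo_raw[["Cost"]]) else NA_real_
    ),
    pcrs = tibble::tibble(
      id = as.integer(pcr_raw[["ID"]]),
      template_name = pcr_raw[["Template"]],
      fwd_oligo = pcr_raw[["Forward Oligo"]],
      rev_oligo = pcr_raw[["Reverse Oligo"]],
      product_length = as.integer(pcr_raw[["Product Length (bp)"]]),
      ta_opt = if ("Mean Anneal Tm (C)" %in% names(pcr_raw))
        as.numeric(pcr_raw[["Mean Anneal Tm (C)"]]) else NA_real_,
      delta = if ("Delta (C)" %in% names(pcr_raw))
        as.numeric(pcr_raw[["Delta (C)"]]) else NA_real_,
      note = if ("Note" %in% names(pcr_raw))
        as.character(pcr_raw[["Note"]]) else NA_character_
    ),
    pieces = tibble::tibble(
      id = as.integer(piece_raw[["ID"]]),
      source_pcr = as.integer(piece_raw[["Source PCR"]]),
      length = as.integer(piece_raw[["Length (bp)"]]),
      piece_kind = piece_raw[["Kind"]]
    ),
    combinations = tibble::tibble(
      construct_name = combo_raw[["Construct"]],
      piece_ids = purrr::map(
        stringr::str_split(combo_raw[["Piece IDs"]], ";"),
        ~ as.integer(stringr::str_trim(.x))
      )
    ),
    strategy = strategy
  )
}

section_tables <- function(bundle) {
  list(
    oligo = stats::setNames(
      tibble::tibble(bundle$oligos$name, bundle$oligos$sequence,
                     bundle$oligos$anneal_tm, bundle$oligos$cost),
      OLIGO_COLS),
    pcr = stats::setNames(
      tibble::tibble(bundle$pcrs$id, bundle$pcrs$template_name,
                     bundle$pcrs$fwd_oligo, bundle$pcrs$rev_oligo,
                     bundle$pcrs$product_length, bundle$pcrs$ta_opt,
                     bundle$pcrs$delta, bundle$pcrs$note),
      PCR_COLS),
    assembly = stats::setNames(
      tibble::tibble(bundle$pieces$id, bundle$pieces$source_pcr,
                     bundle$pieces$length, bundle$pieces$piece_kind),
      PIECE_COLS),
    combinations = stats::setNames(
      tibble::tibble(
        bundle$combinations$construct_name,
        purrr::map_chr(bundle$combinations$piece_ids,
                       ~ paste(.x, collapse = ";"))),
      COMBO_COLS)
  )
}

#' Split a design bundle into the four per-stage CSV files
#'
#' Writes `oligo.csv`, `pcr.csv`, `assembly.csv` and `combinations.csv`
#' into `out_dir`, one design section per file, rows in bundle (file)
#' order.
#'
#' @param bundle a `design_bundle`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a named character vector of the four file paths.
#' @export
write_section_tables <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "design_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop_buildplanr("buildplanr_io_error",
                    sprintf("cannot create directory: %s", out_dir))
  }
  tabs <- section_tables(bundle)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tabs[[nm]], p, na = "", progress = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read a bundle back from split section tables
#'
#' Inverse of [write_section_tables()]: reads the four per-stage CSVs
#' from a directory and reconstructs the `design_bundle`.
#'
#' @param dir directory containing `oligo.csv`, `pcr.csv`,
#'   `assembly.csv`, `combinations.csv`.
#' @inheritParams parse_design
#' @return a `design_bundle`.
#' @export
read_section_tables <- function(dir, strategy = c("pcr_only", "golden_gate",
                                                  "iva_onepot", "aqua")) {
  strategy <- match.arg(strategy)
  rd <- function(name) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(p)) {
      stop_buildplanr("buildplanr_io_error", sprintf("missing file: %s", p))
    }
    readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  }
  oligo_raw <- rd("oligo"); pcr_raw <- rd("pcr")
  piece_raw <- rd("assembly"); combo_raw <- rd("combinations")
  design_bundle(
    oligos = tibble::tibble(
      name = oligo_raw[["Name"]], sequence = oligo_raw[["Sequence"]],
      anneal_tm = as.numeric(oligo_raw[["Anneal Tm (C)"]]),
      cost = as.numeric(oligo_raw[["Cost"]])),
    pcrs = tibble::tibble(
      id = as.integer(pcr_raw[["ID"]]),
      template_name = pcr_raw[["Template"]],
      fwd_oligo = pcr_raw[["Forward Oligo"]],
      rev_oligo = pcr_raw[["Reverse Oligo"]],
      product_length = as.integer(pcr_raw[["Product Length (bp)"]]),
      ta_opt = as.numeric(pcr_raw[["Mean Anneal Tm (C)"]]),
      delta = as.numeric(pcr_raw[["Delta (C)"]]),
      note = as.character(pcr_raw[["Note"]])),
    pieces = tibble::tibble(
      id = as.integer(piece_raw[["ID"]]),
      source_pcr = as.integer(piece_raw[["Source PCR"]]),
      length = as.integer(piece_raw[["Length (bp)"]]),
      piece_kind = piece_raw[["Kind"]]),
    combinations = tibble::tibble(
      construct_name = combo_raw[["Construct"]],
      piece_ids = purrr::map(
        stringr::str_split(combo_raw[["Piece IDs"]], ";"),
        ~ as.integer(stringr::str_trim(.x)))),
    strategy = strategy
  )
}

#' Write a bundle as a single multi-section design file
#'
#' Emits the same single-file, four-section format that [parse_design()]
#' reads, so `parse_design(write_design(b, f))` reproduces `b`.
#'
#' @param bundle a `design_bundle`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_design <- function(bundle, file) {
  stopifnot(inherits(bundle, "design_bundle"))
  tabs <- section_tables(bundle)
  tokens <- unname(SECTION_TOKENS)
  chunks <- character(0)
  for (i in seq_along(tabs)) {
    body <- readr::format_csv(tabs[[i]], na = "")
    chunks <- c(chunks, tokens[i], sub("\n+$", "", body))
  }
  readr::write_lines(chunks, file)
  invisible(file)
}

#' Validate a design bundle
#'
#' Checks the design rules that gate downstream planning and reports all
#' violations rather than throwing: the 96 distinct primer+template
#' capacity, dangling piece/combination/oligo references, nonpositive
#' product or piece lengths, piece lengths disagreeing with their source
#' reaction, negative delta values, annealing optima outside the primers'
#' range, duplicate oligo names, combinations with fewer than two pieces,
#' and pieces never used by any combination.
#'
#' @param bundle a `design_bundle`.
#' @return a `validation_report`: list with `ok` (logical) and
#'   `violations` (tibble with columns `rule`, `item`, `detail`).
#' @export
#' @examples
#' fx <- chromoprotein_like_fixture(dir = tempfile())
#' validate_design(parse_design(fx$path, "golden_gate"))$ok
validate_design <- function(bundle) {
  v <- list()
  add <- function(rule, item, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(rule = rule, item = as.character(item),
                                          detail = detail)
  }

  cap <- design_capacity(bundle)
  if (cap > 96) {
    add("capacity", "bundle",
        sprintf("%d distinct primers+templates exceeds the 96 capacity", cap))
  }
  dup <- bundle$oligos$name[duplicated(bundle$oligos$name)]
  for (d in unique(dup)) add("duplicate_name", d, "oligo name not unique")
  if (any(!nzchar(bundle$oligos$sequence))) {
    add("sequence", "oligos", "empty oligo sequence")
  }
  out_of_range <- bundle$oligos$anneal_tm < 30 | bundle$oligos$anneal_tm > 80 |
    is.na(bundle$oligos$anneal_tm)
  for (nm in bundle$oligos$name[out_of_range]) {
    add("anneal_tm_range", nm, "annealing Tm outside [30, 80] degC")
  }

  tm <- stats::setNames(bundle$oligos$anneal_tm, bundle$oligos$name)
  for (i in seq_len(nrow(bundle$pcrs))) {
    p <- bundle$pcrs[i, ]
    for (ref in c(p$fwd_oligo, p$rev_oligo)) {
      if (!ref %in% bundle$oligos$name) add("reference", ref, sprintf(
        "PCR %d references unknown oligo", p$id))
    }
    if (!is.na(p$product_length) && p$product_length <= 0) {
      add("length", p$id, "nonpositive product length")
    }
    if (!is.na(p$delta) && p$delta < 0) {
      add("delta", p$id, "negative delta")
    }
    if (p$fwd_oligo %in% names(tm) && p$rev_oligo %in% names(tm) &&
        !is.na(p$ta_opt)) {
      lo <- min(tm[[p$fwd_oligo]], tm[[p$rev_oligo]])
      hi <- max(tm[[p$fwd_oligo]], tm[[p$rev_oligo]])
      if (p$ta_opt < lo - 1e-9 || p$ta_opt > hi + 1e-9) {
        add("ta_opt_range", p$id,
            "mean annealing optimum outside the primers' Tm range")
      }
    }
  }

  for (i in seq_len(nrow(bundle$pieces))) {
    pc <- bundle$pieces[i, ]
    if (!pc$source_pcr %in% bundle$pcrs$id) {
      add("reference", pc$id, sprintf("piece references unknown PCR %d",
                                      pc$source_pcr))
    } else {
      src_len <- bundle$pcrs$product_length[bundle$pcrs$id == pc$source_pcr][1]
      if (!is.na(src_len) && !is.na(pc$length) && pc$length != src_len) {
        add("piece_length", pc$id,
            "piece length differs from source PCR product length")
      }
    }
    if (!is.na(pc$length) && pc$length <= 0) {
      add("length", pc$id, "nonpositive piece length")
    }
  }

  used <- integer(0)
  for (i in seq_len(nrow(bundle$combinations))) {
    cb <- bundle$combinations[i, ]
    ids <- cb$piece_ids[[1]]
    used <- c(used, ids)
    if (length(ids) < 2) {
      add("combination_size", cb$construct_name, "fewer than two pieces")
    }
    for (id in setdiff(ids, bundle$pieces$id)) {
      add("reference", cb$construct_name,
          sprintf("combination references unknown piece %d", id))
    }
  }
  for (id in setdiff(bundle$pieces$id, used)) {
    add("unused_piece", id, "piece not referenced by any combination")
  }

  violations <- if (length(v) > 0) dplyr::bind_rows(v) else
    tibble::tibble(rule = character(0), item = character(0),
                   detail = character(0))
  structure(list(ok = nrow(violations) == 0, violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("<validation_report> ok: no violations\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s)\n", nrow(x$violations)))
    print(x$violations, ...)
  }
  invisible(x)
}
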