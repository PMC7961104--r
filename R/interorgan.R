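#' Shared differential metabolites across compartments
#'
#' Per direction (increased/decreased), the intersection of DEM sets for
#' every pair of compartments and for the full set of compartments.
#'
#' @param dems_by_compartment named list of metabolite-layer diff-result
#'   tibbles.
#' @return tibble with `compartments` (plus-joined label), `direction`,
#'   `n`, and list-col `features`.
#' @export
common_dems <- function(dems_by_compartment) {
  comps <- names(dems_by_compartment)
  sets <- lapply(dems_by_compartment, function(d)
    list(increased = d$feature_id[d$class == "increased"],
         decreased = d$feature_id[d$class == "decreased"]))
  combos <- c(if (length(comps) >= 2) utils::combn(comps, 2, simplify = FALSE),
              if (length(comps) >= 3) list(comps))
  rows <- purrr::map(combos, function(cc) {
    purrr::map(c("increased", "decreased"), function(dir) {
      shared <- Reduce(intersect, lapply(sets[cc], `[[`, dir))
      tibble(compartments = paste(cc, collapse = "+"), direction = dir,
             n = length(shared), features = list(sort(shared)))
    }) |> bind_rows()
  })
  bind_rows(rows)
}

#' Pearson correlation of fold changes across two compartments
#'
#' Correlates log2 fold changes of the features shared by two compartments,
#' optionally restricted to a feature set (e.g. the DEMs of the second
#' compartment, mirroring a blood-vs-organ comparison).
#'
#' @param fc_a,fc_b named numeric vectors of log2 fold changes.
#' @param restrict_to optional feature set to intersect with.
#' @return list with `r` (Pearson) and `n` (features used).
#' @export
crosscompartment_correlation <- function(fc_a, fc_b, restrict_to = NULL) {
  shared <- intersect(names(fc_a), names(fc_b))
  if (!is.null(restrict_to)) shared <- intersect(shared, restrict_to)
  assert_that(length(shared) >= 3,
              "need at least 3 shared features after restriction")
  list(r = cor(fc_a[shared], fc_b[shared], method = "pearson"),
       n = length(shared))
}

#' Built-in inter-organ metabolic cycle definitions
#'
#' Ships the three fasting-state cycles between liver and skeletal muscle
#' via the blood as editable YAML fixtures: the glucose-alanine cycle
#' (muscle releases alanine, liver regenerates glucose; transporters
#' Asct1/Asct2, enzymes Gpt/Gpt2), the glucose-lactate (Cori) cycle
#' (lactate via Slc16a1, Ldha) and the ketone body cycle (liver produces
#' acetoacetate/3-hydroxybutyrate from fatty acid degradation via Hmgcs2,
#' Hmgcl, Bdh1; transporters Slc16a6/Slc16a7).
#'
#' @param dir directory holding cycle YAML files (defaults to the files
#'   installed with the package).
#' @return list of `cycle_definition` objects.
#' @export
built_in_cycles <- function(dir = system.file("extdata", "cycles",
                                              package = "transomix")) {
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  lapply(files, read_cycle_definition)
}

#' @rdname built_in_cycles
#' @param path path to one cycle YAML file.
#' @export
read_cycle_definition <- function(path) {
  raw <- yaml::read_yaml(path)
  legs <- bind_rows(lapply(raw$legs, function(l) {
    tibble(compartment = l$compartment, role = l$role,
           metabolite_ids = list(as.character(l$metabolites %||% character())),
           enzyme_protein_ids = list(as.character(l$enzymes %||% character())),
           transporter_gene_ids =
             list(as.character(l$transporters %||% character())),
           flow = l$flow %||% NA_character_)
  }))
  assert_that(length(unique(legs$compartment)) >= 2,
              "a cycle needs at least 2 compartments")
  assert_that(any(legs$role == "carrier"),
              "a cycle needs a carrier (blood) leg")
  structure(list(name = raw$name, legs = legs), class = "cycle_definition")
}

#' @export
print.cycle_definition <- function(x, ...) {
  cat(sprintf("<cycle_definition: %s, %d legs (%s)>\n", x$name,
              nrow(x$legs), paste(x$legs$compartment, collapse = ", ")))
  invisible(x)
}

# change direction of one feature in one diff table; "not_measured" when
# the feature is absent, "not significant" when unchanged
lookup_change <- function(diff_tbl, id) {
  if (is.null(diff_tbl) || id %nin% diff_tbl$feature_id)
    return("not_measured")
  cls <- diff_tbl$class[match(id, diff_tbl$feature_id)]
  if (cls == "unchanged") "not significant" else cls
}

#' Structured report for an inter-organ metabolic cycle
#'
#' Fills each leg's member change directions from the per-compartment
#' differential results and renders a per-metabolite verdict for every
#' carried metabolite: `imbalance` when the carrier (blood) direction
#' matches the releasing organ's pool and opposes the uptaking organ's pool
#' (the signature of release/uptake imbalance), `insufficient_data` when
#' any member (metabolite, enzyme or transporter) of a leg carrying that
#' metabolite went unmeasured, otherwise `consistent`. The
#' verdict is a pure function of the structured change table.
#'
#' @param cycle a `cycle_definition`.
#' @param diff_by_compartment nested list:
#'   `diff_by_compartment[[compartment]][[layer]]` diff-result tibbles
#'   (layers `metabolite`, `protein`, `transcript` used).
#' @return list with `cycle`, `members` (long change table) and `verdicts`
#'   (per carried metabolite).
#' @export
cycle_report <- function(cycle, diff_by_compartment) {
  missing <- setdiff(cycle$legs$compartment, names(diff_by_compartment))
  assert_that(length(missing) == 0,
              paste0("cycle references compartment(s) absent from the ",
                     "study: ", paste(missing, collapse = ", ")))
  members <- cycle$legs |>
    mutate(leg = row_number()) |>
    tidyr::pivot_longer(c("metabolite_ids", "enzyme_protein_ids",
                          "transporter_gene_ids"),
                        names_to = "kind", values_to = "id") |>
    tidyr::unnest(cols = "id") |>
    mutate(kind = dplyr::recode(.data$kind,
                                metabolite_ids = "metabolite",
                                enzyme_protein_ids = "enzyme",
                                transporter_gene_ids = "transporter"))
  members$change <- pmap(members, function(compartment, kind, id, ...) {
    layer <- switch(kind, metabolite = "metabolite", enzyme = "protein",
                    transporter = "transcript")
    lookup_change(diff_by_compartment[[compartment]][[layer]], id)
  }) |> unlist()
  carrier <- cycle$legs$compartment[cycle$legs$role == "carrier"][1]
  carried <- unique(unlist(
    cycle$legs$metabolite_ids[cycle$legs$role == "carrier"]))
  # producer/consumer compartments are resolved per metabolite: a compartment
  # can release one metabolite of the cycle and take up another
  legs_with <- function(role, met) {
    keep <- cycle$legs$role == role &
      map_lgl(cycle$legs$metabolite_ids, ~ met %in% .x)
    unique(cycle$legs$compartment[keep])
  }
  verdicts <- purrr::map(carried, function(met) {
    producers <- legs_with("producer", met)
    consumers <- legs_with("consumer", met)
    get_change <- function(comp) {
      row <- members |>
        filter(.data$compartment == comp, .data$kind == "metabolite",
               .data$id == met)
      if (nrow(row) == 0) NA_character_ else row$change[1]
    }
    ch_carrier <- get_change(carrier)
    ch_prod <- map_chr(producers, get_change)
    ch_cons <- map_chr(consumers, get_change)
    chs <- c(ch_carrier, ch_prod, ch_cons)
    chs <- chs[!is.na(chs)]
    # a leg is insufficient when any of its members (metabolite, enzyme or
    # transporter) went unmeasured in its compartment
    legs_of_met <- which(map_lgl(cycle$legs$metabolite_ids,
                                 ~ met %in% .x))
    leg_changes <- members$change[members$leg %in% legs_of_met]
    verdict <- if (any(c(chs, leg_changes) == "not_measured")) {
      "insufficient_data"
    } else if (!is.na(ch_carrier) &&
               ch_carrier %in% c("increased", "decreased") &&
               any(ch_prod == ch_carrier, na.rm = TRUE) &&
               any(ch_cons == flip_change(ch_carrier), na.rm = TRUE)) {
      "imbalance"
    } else {
      "consistent"
    }
    tibble(metabolite = met, carrier_change = ch_carrier, verdict = verdict)
  }) |> bind_rows()
  list(cycle = cycle$name, members = members, verdicts = verdicts)
}
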