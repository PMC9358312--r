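# The ten M1-M5 model specifications (five families at the individual and
# dyadic level), their control/intermediate comparators, and the prediction
# ledger rows the pipeline summary mirrors.

model_spec <- function(name, level, family, response, full,
                       intermediate = NULL, control) {
  structure(list(name = name, level = level, family = family,
                 response = response, full = full,
                 intermediate = intermediate, control = control),
            class = "model_spec")
}

#' Default model suite specification
#'
#' Encodes the ten regression structures of the analysis. At the
#' individual level (one row per individual; attention models use one row
#' per individual and modality): M1 repertoire size, M2 attention
#' accounting (with the three modality interactions), M3 flexibility (beta
#' regression), M4 sequence use, M5 response elicitation. At the dyadic
#' level the same five families with maternal kinship, bond and species as
#' predictors and age difference plus sex combination as controls. Each
#' full model is compared against a controls-only model (and, for M2 and
#' M5, an intermediate model).
#'
#' @return A list of `model_spec` objects, one per model.
#' @export
default_model_specs <- function() {
  ind_ctl <- c("sex", "z_effort")
  dy_pred <- c("maternal_kin", "z_bond", "species")
  dy_ctl <- c("z_age_difference", "sex_combination")
  list(
    model_spec("M1-Ind", "individual", "binomial",
               c("repertoire_used", "repertoire_possible"),
               full = c("z_centrality", "z_age", "species", ind_ctl),
               control = ind_ctl),
    model_spec("M2-Ind", "individual_modality", "binomial",
               c("attended", "assessed"),
               full = c("modality", "z_centrality", "z_age", "species",
                        "modality:z_centrality", "modality:z_age",
                        "modality:species", "sex"),
               intermediate = c("modality", "z_centrality", "z_age",
                                "species", "sex"),
               control = "sex"),
    model_spec("M3-Ind", "individual", "beta", "flexibility",
               full = c("z_centrality", "z_age", "species", ind_ctl),
               control = ind_ctl),
    model_spec("M4-Ind", "individual", "binomial",
               c("in_sequence", "sequence_assessed"),
               full = c("z_centrality", "z_age", "species", "sex"),
               control = "sex"),
    model_spec("M5-Ind", "individual", "binomial",
               c("responded", "produced"),
               full = c("rep_prop", "att_visual_prop", "flexibility",
                        "seq_prop", "z_centrality", "z_age", "species", "sex"),
               intermediate = c("z_centrality", "z_age", "species", "sex"),
               control = "sex"),
    model_spec("M1-Dyad", "dyad", "binomial",
               c("repertoire_used", "repertoire_possible"),
               full = c(dy_pred, dy_ctl, "z_effort"),
               control = c(dy_ctl, "z_effort")),
    model_spec("M2-Dyad", "dyad_modality", "binomial",
               c("attended", "assessed"),
               full = c("modality", dy_pred, "modality:maternal_kin",
                        "modality:z_bond", "modality:species", dy_ctl),
               intermediate = c("modality", dy_pred, dy_ctl),
               control = dy_ctl),
    model_spec("M3-Dyad", "dyad", "beta", "flexibility",
               full = c(dy_pred, dy_ctl, "z_effort"),
               control = c(dy_ctl, "z_effort")),
    model_spec("M4-Dyad", "dyad", "binomial",
               c("in_sequence", "sequence_assessed"),
               full = c(dy_pred, dy_ctl),
               control = dy_ctl),
    model_spec("M5-Dyad", "dyad", "binomial",
               c("responded", "produced"),
               full = c("rep_prop", "att_visual_prop", "flexibility",
                        "seq_prop", dy_pred, dy_ctl),
               intermediate = c(dy_pred, dy_ctl),
               control = dy_ctl)
  )
}

#' Prediction ledger
#'
#' The fourteen directional predictions the pipeline summary reports: more
#' social integration and older age predict more complex gestural use at
#' the individual level (four complexity measures); better dyadic
#' relationship quality predicts more complex use at the dyadic level
#' (four measures); and more effective communication (eliciting responses)
#' is predicted by gestural complexity, social integration and age at the
#' individual level and by complexity, kinship and bonds at the dyadic
#' level. All predictions are positive-signed; the summary records the
#' estimated sign and whether the 95% interval supports it.
#'
#' @return Data frame with `prediction`, `model` and the coefficient
#'   `terms` (comma-separated) each prediction is judged on.
#' @export
prediction_ledger <- function() {
  data.frame(
    prediction = c(
      "individual: centrality/age -> repertoire size",
      "individual: centrality/age -> attention accounting",
      "individual: centrality/age -> flexibility",
      "individual: centrality/age -> sequence use",
      "dyad: kin/bond -> repertoire size",
      "dyad: kin/bond -> attention accounting",
      "dyad: kin/bond -> flexibility",
      "dyad: kin/bond -> sequence use",
      "individual: gestural complexity -> response",
      "individual: social integration -> response",
      "individual: age -> response",
      "dyad: gestural complexity -> response",
      "dyad: kin -> response",
      "dyad: bond -> response"),
    model = c("M1-Ind", "M2-Ind", "M3-Ind", "M4-Ind",
              "M1-Dyad", "M2-Dyad", "M3-Dyad", "M4-Dyad",
              "M5-Ind", "M5-Ind", "M5-Ind",
              "M5-Dyad", "M5-Dyad", "M5-Dyad"),
    terms = c(
      "z_centrality,z_age", "z_centrality,z_age",
      "z_centrality,z_age", "z_centrality,z_age",
      "maternal_kinTRUE,z_bond", "maternal_kinTRUE,z_bond",
      "maternal_kinTRUE,z_bond", "maternal_kinTRUE,z_bond",
      "rep_prop,att_visual_prop,flexibility,seq_prop",
      "z_centrality", "z_age",
      "rep_prop,att_visual_prop,flexibility,seq_prop",
      "maternal_kinTRUE", "z_bond"),
    stringsAsFactors = FALSE)
}

#' Write model specifications to YAML
#'
#' @param specs list of model specs (default [default_model_specs()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_specs <- function(specs = default_model_specs(), path) {
  yaml::write_yaml(lapply(specs, function(s) {
    list(name = s$name, level = s$level, family = s$family,
         response = as.list(s$response), full = as.list(s$full),
         intermediate = if (is.null(s$intermediate)) NULL
           else as.list(s$intermediate),
         control = as.list(s$control))
  }), path)
  invisible(path)
}

#' Read model specifications from YAML
#'
#' @param path YAML file written by [write_model_specs()] (the packaged
#'   default lives at `system.file("extdata", "models.yaml",
#'   package = "apegest")`).
#' @return A list of `model_spec` objects.
#' @export
read_model_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    model_spec(s$name, s$level, s$family, unlist(s$response),
               full = unlist(s$full),
               intermediate = if (is.null(s$intermediate)) NULL
                 else unlist(s$intermediate),
               control = unlist(s$control))
  })
}
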