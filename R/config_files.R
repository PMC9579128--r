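# Readers for the shipped, human-editable material and reaction-channel
# configuration documents. The built-in accessors load (and cache) these
# files, so editing the shipped YAML genuinely changes the physics tables.

#' Read materials from a YAML document
#'
#' One document entry per material: `density_g_cm3` and a `composition`
#' mapping of element to mass fraction.
#'
#' @param path YAML file path; defaults to the shipped table.
#' @return A named list of `nd_material` objects.
#' @export
read_materials <- function(path = system.file("extdata", "materials.yml",
                                              package = "nanodosim",
                                              mustWork = TRUE)) {
  raw <- yaml::read_yaml(path)
  lapply(setNames(names(raw), names(raw)), function(nm) {
    m <- raw[[nm]]
    material(nm, m$density_g_cm3, unlist(m$composition))
  })
}

#' Read reaction channels from a YAML document
#'
#' @param path YAML file path; defaults to the shipped table.
#' @return A named list of [reaction_channel()] objects.
#' @export
read_reaction_channels <- function(path = system.file(
  "extdata", "reaction_channels.yml", package = "nanodosim",
  mustWork = TRUE
)) {
  raw <- yaml::read_yaml(path)
  lapply(setNames(names(raw), names(raw)), function(nm) {
    ch <- raw[[nm]]
    reaction_channel(nm, ch$projectile, ch$target_nuclide,
                     unlist(ch$products), ch$sigma_barn,
                     ch$alpha_multiplicity, ch$q_value_mev)
  })
}

shipped_materials <- function() {
  if (is.null(the$materials)) the$materials <- read_materials()
  the$materials
}
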