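# Shared fixtures. Expensive objects are built once per test run.

# A small, fast scenario (30 kb genomes) for unit tests; the full-size
# study conditions are exercised in test-acceptance.R.
small_config <- function(seed = 101L, ...) {
  sim_config(seed = seed, genome_len = 30000L, te_len = 4000L,
             ltr_len = 250L, ...)
}

fixture_cache <- new.env(parent = emptyenv())

with_seed_local <- htte:::with_seed

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

small_scenario <- function() {
  cached("small_scenario", build_ht_scenario(small_config()))
}

test_profiles <- function() default_profiles()

# The published inventory of 15 donor/recipient/cluster records, with
# element ids tying the multi-call clusters to their RT trees.
grass_rice_calls <- function() {
  ht_calls(
    donor_taxon = c("E_haploclada", "Z_bulbosa", "M_ambigua", "Z_bulbosa",
                    "E_meyeriana", "E_haploclada", "C_citratus", "C_citratus",
                    "E_haploclada", "E_pyramidalis", "E_haploclada",
                    "I_membranaceum", "I_membranaceum", "C_pilosus",
                    "C_setigerus"),
    recipient_taxon = c("O_punctata", "O_brachyantha", "O_nivara",
                        "O_rufipogon", "O_sativa", "O_brachyantha",
                        "O_sativa", "O_nivara", "O_glumaepatula",
                        "O_punctata", "O_punctata", "O_rufipogon",
                        "O_sativa", "O_sativa", "O_nivara"),
    cluster_id = c("CL010", "CL010", "CL129", "CL129", "CL129", "CL212",
                   "CL025", "CL025", "CL112", "CL148", "CL148", "CL102",
                   "CL102", "CL102", "CL329"),
    mean_identity = c(98.7, 98.9, 97.8, 99.1, 98.6, 99.3, 99.3, 99.3,
                      97.3, 98.4, 98.1, 97.0, 97.8, 97.3, 97.1),
    donor_element = c(NA, NA, NA, NA, NA, NA, "Ccit_el1", "Ccit_el1", NA,
                      "Epyr_el", "Ehap_el", "Imem_el", "Imem_el", "Cpil_el",
                      NA),
    recipient_element = c(NA, NA, NA, NA, NA, NA, "Osat_el", "Oniv_el", NA,
                          "Opun_el1", "Opun_el2", "Oruf_el", "Osat_el1",
                          "Osat_el2", NA))
}

# RT trees for the three multi-call clusters: recipients nested inside
# the donor copies; the two CL102 transfer lineages sit in different
# parts of the cluster's diversity.
grass_rice_trees <- function() {
  list(
    CL025 = ape::read.tree(
      text = "((Ccit_el1,(Ccit_el2,((Osat_el,Oniv_el),Oruf_el))),out1,out2);"),
    CL102 = ape::read.tree(
      text = "((Imem_el,out1,(Osat_el1,Oruf_el)),(Cpil_el,out2,Osat_el2));"),
    CL148 = ape::read.tree(
      text = "((Epyr_el,(Opun_el1,(Opun_el2,Ehap_el))),out1,out2);"))
}

# Write a temporary file of lines, cleaned up by withr-style deferral.
tmpfile <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
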