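#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic datasets the analyses run on.
#
# The interspecific dataset emulates the broad comparative design: one
# male and one female pectoral outline for each of 21 skate species on a
# pure-birth phylogeny, with species-specific dimorphism magnitudes
# spanning a five-fold range. The ontogenetic dataset emulates a
# single-species growth series (21 males, 22 females, 50.6-109.5 mm disc
# width) with two-phase clasper growth breaking at 84 mm, plus nine
# endoskeletal traits under sex-specific log-log allometries.

library(skatemorph)

seed <- 1L
data_dir <- "results/data"

message("simulating interspecific dataset (seed ", seed, ") ...")
spec <- synthetic_spec(seed = seed)
inter <- simulate_interspecific(spec, file.path(data_dir, "interspecific"))
message("  ", length(inter$configs), " outlines for ", spec$n_species,
        " species -> ", file.path(data_dir, "interspecific"))

message("simulating ontogenetic dataset ...")
ont <- simulate_ontogeny(spec, file.path(data_dir, "ontogeny"))
message("  ", length(ont$configs), " outlines (",
        sum(ont$metadata$sex == "male"), " male / ",
        sum(ont$metadata$sex == "female"), " female) -> ",
        file.path(data_dir, "ontogeny"))

message("simulating endoskeletal measurements ...")
simulate_skeletal_traits(spec, file.path(data_dir, "ontogeny"))
message("  9 traits per specimen -> ",
        file.path(data_dir, "ontogeny", "skeletal.csv"))
message("done; ground truth recorded in the truth*.txt manifests")
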