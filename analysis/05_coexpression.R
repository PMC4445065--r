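#!/usr/bin/env Rscript
# Co-expression network over a synthetic SOX expression matrix: a SOXE
# block (SOX8/9/10) and a SOXB block (SOX1/2/21) of correlated genes plus
# unrelated SOX genes, thresholded into strong (r2 > 0.4) and weak
# (r2 > 0.1) edges.

suppressPackageStartupMessages(library(dimerscreen))

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

genes <- c("SOX8", "SOX9", "SOX10", "SOX1", "SOX2", "SOX21",
           "SOX4", "SOX6", "SOX18")
x <- simulate_expression(length(genes), n_samples = 300,
                         blocks = list(1:3, 4:6), within_r = 0.7,
                         seed = seed)
rownames(x) <- genes

r2 <- pairwise_r2(x)
net <- build_network(r2, strong = 0.4, weak = 0.1)
print(net)

write_results_tsv(as.data.frame(round(r2, 4)), file.path(out, "r2_matrix.tsv"),
                  seed = seed, params = list(n_samples = 300,
                                             within_r = 0.7))
write_results_tsv(net$edges, file.path(out, "coexpression_edges.tsv"),
                  seed = seed, params = list(strong = 0.4, weak = 0.1))
cat(sprintf("strong edges: %s\n",
            paste(net$edges$gene_i[net$edges$class == "strong"],
                  net$edges$gene_j[net$edges$class == "strong"],
                  sep = "-", collapse = ", ")))
cat("wrote", file.path(out, "coexpression_edges.tsv"), "\n")
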