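# Published per-sample co-occurrence results used as reference values:
# gene pair, sample column, observed event count k, BH-adjusted
# single-co-occurrence p-value (printed, 3 s.f.), and the printed estimated
# p-value for k events. Printed inputs are themselves rounded, so checks
# propagate +/- half a unit in the last printed digit of p_adj.
published_cooccurrence <- function() {
  txt <- "
gene_a gene_b sample k p_adj p_est
MACROD2 BRAF a 1 3.02e-3 3.02e-3
MACROD2 BRAF b 1 3.34e-3 3.34e-3
MACROD2 BRAF c 2 6.59e-4 4.34e-7
RBFOX1 BRAF b 1 2.29e-3 2.29e-3
RBFOX1 BRAF c 2 8.30e-4 6.88e-7
PTPRD WWC3 b 1 2.58e-3 2.58e-3
PTPRD WWC3 c 2 2.38e-4 5.68e-8
NEDD4L BRAF a 1 9.56e-4 9.56e-4
NEDD4L BRAF b 3 7.81e-4 4.77e-10
NEDD4L ABCG2 a 1 9.33e-4 9.33e-4
NEDD4L ABCG2 b 2 2.67e-4 7.11e-8
NEDD4L TENM2 a 1 2.96e-3 2.96e-3
NEDD4L TENM2 b 2 2.96e-3 8.79e-6
TENM2 BRAF a 1 1.43e-3 1.43e-3
TENM2 BRAF b 2 2.33e-3 5.44e-6
MITF LPAR1 a 3 1.26e-3 2.00e-9
OSBPL9 FAM180A a 2 1.01e-3 1.02e-6
SH3PXD2A WDR41 a 2 8.40e-4 7.06e-7
LOC105376514 MITF a 2 7.20e-4 5.18e-7
LOC105376514 ATG10 a 2 6.30e-4 3.97e-7
TEAD1 BRAF a 2 6.40e-4 4.10e-7
CPNE8 BRAF a 2 5.04e-4 2.54e-7
CPNE8 FBXO10 a 2 4.58e-4 2.10e-7
ABCC4 ANXA4 a 2 2.33e-4 5.44e-8
DOK6 NR2F1-AS1 a 2 3.88e-4 1.50e-7
ROCK2 COLQ a 2 3.60e-4 1.30e-7
RASGRP3 MITF a 2 2.29e-4 5.25e-8
LOC101927967 MITF a 2 3.15e-4 9.92e-8
LOC101927967 SLC24A2 a 2 2.96e-4 8.79e-8
LOC101927967 CNTNAP3B a 2 2.80e-4 7.84e-8
LOC101927967 LPAR1 a 2 2.65e-4 7.04e-8
PLCL1 LOC105372948 a 2 2.52e-4 6.35e-8
SYN3 HTR1F a 2 4.94e-4 2.44e-7
MITF SLC24A2 a 2 3.36e-4 1.13e-7
PTPN13 ATG10 a 2 7.37e-4 5.43e-7
ATG10 NR2F1-AS1 a 2 4.20e-4 1.76e-7
TBXAS1 BRAF a 2 5.60e-4 3.14e-7
TBXAS1 ST18 a 2 1.68e-3 2.82e-6
AGBL4 NEDD4L b 2 2.80e-4 7.84e-8
ANXA9 ABCA11P b 2 2.52e-3 6.35e-6
KIN LOC102724861 b 2 3.86e-4 1.49e-7
ITPR2 LOC102723906 b 2 5.60e-4 3.14e-7
MGAT4C BRAF b 2 4.31e-4 1.86e-7
HS3ST3A1 NEDD4L b 2 2.24e-4 5.02e-8
ITGA3 LOC105377171 b 2 3.36e-4 1.13e-7
ITGA3 GRB10 b 2 3.29e-4 1.09e-7
NEDD4L LOC102724861 b 2 6.83e-4 4.66e-7
NEDD4L ZC3H12B b 2 1.22e-3 1.48e-6
LOC102724861 TENM2 b 2 1.15e-3 1.31e-6
LOC102724861 PDE1C b 2 8.00e-4 6.40e-7
MACROD2 TENM2 b 2 1.41e-2 1.99e-4
LOC105377171 GRB10 b 2 2.43e-4 5.93e-8
LOC105377180 KDM5C b 2 4.15e-4 1.72e-7
KIAA1524 MEGF9 b 2 3.73e-4 1.39e-7
IGSF11 EYS b 2 5.08e-3 2.58e-5
KALRN BRAF b 2 1.24e-3 1.55e-6
ABCA11P LOC105374483 b 2 1.68e-3 2.82e-6
ABCG2 BRAF b 2 5.42e-4 2.94e-7
ABCG2 NSMCE2 b 2 5.89e-4 3.47e-7
LOC102723906 EYS b 2 3.38e-3 1.14e-5
LOC105377865 ZC3H12B b 2 2.14e-3 4.60e-6
GRB10 ZC3H12B b 2 6.05e-4 3.67e-7
CNTNAP2 ZC3H12B b 2 7.13e-3 5.08e-5
SLC26A7 ZFPM2-AS1 b 2 4.80e-4 2.30e-7
"
  read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

# half a unit in the last digit of a value printed to 3 significant figures
half_ulp3 <- function(x) 10^(floor(log10(abs(x))) - 2) / 2

# adjusted Rand index between two label vectors
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
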