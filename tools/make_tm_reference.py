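#!/usr/bin/env python
"""Freeze an independent nearest-neighbour Tm reference table.

Computes melting temperatures for a fixed set of random 12-18-mer primers
with Bio.SeqUtils.MeltingTemp (SantaLucia & Hicks 2004 table DNA_NN4,
Owczarzy 2008 salt correction, method 7) under the package's default ionic
conditions (50 mM monovalent, 1.5 mM Mg2+, 0.2 mM dNTP, 200 nM primer;
CT/4 duplex convention, so dnac1 = 50 nM with dnac2 = 0). Output goes to
tests/testthat/tm_reference.tsv and is used as the cross-implementation
oracle in the test suite.

Usage: python tools/make_tm_reference.py
"""
import random

from Bio.SeqUtils import MeltingTemp as mt

random.seed(20260401)

def revcomp(s):
    return s.translate(str.maketrans("ACGT", "TGCA"))[::-1]

rows = [("AAAAAACTGCAG",)]  # worked example: poly-A flank + PstI site
seen = {rows[0][0]}
while len(rows) < 1001:
    k = random.randint(12, 18)
    s = "".join(random.choice("ACGT") for _ in range(k))
    if s in seen or s == revcomp(s):  # palindromes use a different CT term
        continue
    seen.add(s)
    rows.append((s,))

with open("tests/testthat/tm_reference.tsv", "w") as fh:
    fh.write("seq\ttm\n")
    for (s,) in rows:
        tm = mt.Tm_NN(s, nn_table=mt.DNA_NN4, Na=50, Mg=1.5, dNTPs=0.2,
                      dnac1=50, dnac2=0, saltcorr=7)
        fh.write(f"{s}\t{tm:.6f}\n")
print(f"wrote {len(rows)} reference Tms")
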