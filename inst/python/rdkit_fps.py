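"""Batch fingerprint computation over RDKit.

Reads a tab-separated file of (id, smiles) rows, computes the requested
fingerprint types at the requested width, and prints one line per
(id, type): ``id<TAB>type<TAB>space-separated 0-based on-bit positions``
(the position list may be empty). Rows whose SMILES cannot be parsed yield
``id<TAB>__parse_error__<TAB>smiles``.

Usage: python rdkit_fps.py INPUT_TSV TYPES_CSV N_BITS STANDARDIZE(0|1)
"""

import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator as rfg

RDLogger.DisableLog("rdApp.*")


def make_generators(types, n_bits):
    gens = {}
    for t in types:
        if t == "rdkit":
            gens[t] = rfg.GetRDKitFPGenerator(fpSize=n_bits)
        elif t == "morgan":
            gens[t] = rfg.GetMorganGenerator(radius=2, fpSize=n_bits)
        elif t == "atompair":
            gens[t] = rfg.GetAtomPairGenerator(fpSize=n_bits)
        elif t == "torsion":
            gens[t] = rfg.GetTopologicalTorsionGenerator(fpSize=n_bits)
        elif t == "layered":
            gens[t] = ("layered", n_bits)  # no generator API; handled below
        elif t == "featmorgan":
            gens[t] = rfg.GetMorganGenerator(
                radius=2, fpSize=n_bits,
                atomInvariantsGenerator=rfg.GetMorganFeatureAtomInvGen())
        elif t == "ecfp4":
            # distinct generator settings so ECFP4 and Morgan differ
            gens[t] = rfg.GetMorganGenerator(
                radius=2, fpSize=n_bits, includeRedundantEnvironments=True)
        else:
            sys.stderr.write("unknown fingerprint type: %s\n" % t)
            sys.exit(2)
    return gens


def largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) <= 1:
        return mol
    return max(frags, key=lambda m: m.GetNumHeavyAtoms())


def main():
    path, types_csv, n_bits, standardize = sys.argv[1:5]
    types = types_csv.split(",")
    n_bits = int(n_bits)
    standardize = standardize == "1"
    gens = make_generators(types, n_bits)
    out = sys.stdout
    with open(path) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            cid, smi = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.write("%s\t__parse_error__\t%s\n" % (cid, smi))
                continue
            if standardize:
                mol = largest_fragment(mol)
            for t in types:
                g = gens[t]
                if isinstance(g, tuple):
                    fp = Chem.LayeredFingerprint(mol, fpSize=n_bits)
                else:
                    fp = g.GetFingerprint(mol)
                bits = " ".join(str(b) for b in fp.GetOnBits())
                out.write("%s\t%s\t%s\n" % (cid, t, bits))


if __name__ == "__main__":
    main()
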