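#!/usr/bin/env python
"""Distance-geometry conformer embedding helper.

Usage: gen_conformers.py IN.sdf OUT.sdf N SEED

Reads the first record of IN.sdf (explicit hydrogens expected), embeds N
conformers with ETKDGv3 at the given random seed, minimizes them with
MMFF94 and writes one SDF record per conformer with an <energy> data
field (kcal/mol). Atom order is preserved.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem


def main(argv):
    if len(argv) != 5:
        sys.stderr.write(__doc__)
        return 2
    fin, fout, n, seed = argv[1], argv[2], int(argv[3]), int(argv[4])
    supp = Chem.SDMolSupplier(fin, removeHs=False, sanitize=True)
    mol = next((m for m in supp if m is not None), None)
    if mol is None:
        sys.stderr.write("could not read a molecule from %s\n" % fin)
        return 2
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    params.numThreads = 1
    params.useRandomCoords = True
    ids = AllChem.EmbedMultipleConfs(mol, numConfs=n, params=params)
    if len(ids) == 0:
        sys.stderr.write("embedding produced no conformers\n")
        return 3
    res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=500)
    writer = Chem.SDWriter(fout)
    writer.SetKekulize(True)
    for cid, (_, energy) in zip(ids, res):
        mol.SetProp("energy", "%.6f" % energy)
        writer.write(mol, confId=cid)
    writer.close()
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
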