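"""Molecular-graph backend for the fragcompare R package.

Every subcommand reads one JSON document and writes one JSON document:

    python chemtools.py <command> <infile> <outfile>

The input is {"smiles": [...], "options": {...}} unless noted otherwise.
All chemistry is delegated to RDKit; the analysis logic lives on the R side.
"""

import gzip
import json
import math
import pickle
import sys

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import (Crippen, Descriptors, Lipinski, MACCSkeys,
                        rdFingerprintGenerator, rdMolDescriptors)
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

ELEMENT_WHITELIST = {"H", "B", "C", "N", "O", "F", "Si", "P", "S",
                     "Cl", "Se", "Br", "I"}

# ---------------------------------------------------------------------------
# RECAP cleavage rules.
#
# Each rule is a SMARTS with two mapped atoms; the (acyclic) bond between the
# atoms mapped :1 and :2 is the cleavable bond.  The environments follow the
# published RECAP definitions as concretized in the standard toolkit, but the
# engine here is bond-based: broken bond ends are capped with hydrogen, so
# the heavy atoms of the leaves always partition the parent's heavy atoms.
# The ether rule excludes ester alkyl oxygens so that esters cleave only at
# the acyl C-O bond.
# ---------------------------------------------------------------------------
RECAP_RULES = [
    ("urea", "[#7;+0;D2,D3:1]!@[C:2](!@=O)!@[#7;+0;D2,D3]"),
    ("amide", "[C;!$(C([#7])[#7]):1](=!@[O])!@[#7;+0;!D1:2]"),
    ("ester", "[C:1](=!@[O])!@[O;+0;D2:2]"),
    ("amine", "[N;!D1;+0;!$(N-C=[#7,#8,#15,#16]);!$(N-[S,P]=O):1]-!@[#6:2]"),
    ("ether", "[#6:1]-!@[O;+0;D2;!$(O-C=[O,N,S]):2]-!@[#6]"),
    ("olefin", "[C:1]=!@[C:2]"),
    ("aromatic_N_aliphatic_C", "[n;+0:1]-!@[C:2]"),
    ("lactam_N_aliphatic_C", "[O]=[C]-@[N;+0:1]-!@[C:2]"),
    ("aromatic_C_aromatic_C", "[c:1]-!@[c:2]"),
    ("quaternary_N", "[N;+1;D4:1]-!@[#6:2]"),
    ("sulfonamide", "[#7;+0;!D1:1]-!@[S:2](=O)=O"),
]

_recap_pats = None


def recap_patterns():
    global _recap_pats
    if _recap_pats is None:
        pats = []
        for name, sma in RECAP_RULES:
            pat = Chem.MolFromSmarts(sma)
            i1 = [i for i, a in enumerate(pat.GetAtoms())
                  if a.GetAtomMapNum() == 1][0]
            i2 = [i for i, a in enumerate(pat.GetAtoms())
                  if a.GetAtomMapNum() == 2][0]
            pats.append((name, pat, i1, i2))
        _recap_pats = pats
    return _recap_pats


def cleavable_bonds(mol):
    """(bond_idx, rule_name) pairs, deduplicated, deterministic order."""
    seen = set()
    out = []
    for name, pat, i1, i2 in recap_patterns():
        for match in mol.GetSubstructMatches(pat, uniquify=False):
            b = mol.GetBondBetweenAtoms(match[i1], match[i2])
            if b is None or b.IsInRing():
                continue
            key = (b.GetIdx(), name)
            if key not in seen:
                seen.add(key)
                out.append(key)
    return sorted(out)


def break_bonds(mol, bond_idxs, order=None):
    """Break the given bonds simultaneously, cap ends with explicit H,
    and return the resulting fragments (implicit-H molecules)."""
    info = []
    for bi in bond_idxs:
        b = mol.GetBondWithIdx(bi)
        nh = 2 if b.GetBondType() == Chem.BondType.DOUBLE else 1
        info.append((b.GetBeginAtomIdx(), b.GetEndAtomIdx(), nh))
    if order is not None:
        info = [info[i] for i in order]
    em = Chem.RWMol(mol)
    em.BeginBatchEdit()
    for a1, a2, nh in info:
        em.RemoveBond(a1, a2)
        for a in (a1, a2):
            for _ in range(nh):
                h = em.AddAtom(Chem.Atom(1))
                em.AddBond(a, h, Chem.BondType.SINGLE)
    em.CommitBatchEdit()
    m = em.GetMol()
    Chem.SanitizeMol(m)
    return Chem.GetMolFrags(Chem.RemoveHs(m), asMols=True)


def recap_leaves(mol, order_rng=None):
    """Leaf fragments of the hierarchical decomposition (SMILES, with
    per-parent multiplicity).  The undecomposable parent yields []."""
    top = cleavable_bonds(mol)
    if not top:
        return []
    leaves = []
    stack = [mol]
    while stack:
        m = stack.pop()
        bonds = cleavable_bonds(m)
        if not bonds:
            leaves.append(Chem.MolToSmiles(m))
            continue
        idxs = sorted({bi for bi, _ in bonds})
        order = None
        if order_rng is not None:
            order = list(range(len(idxs)))
            order_rng.shuffle(order)
        for frag in break_bonds(m, idxs, order=order):
            stack.append(frag)
    return sorted(leaves)


# ---------------------------------------------------------------------------
# Standardization (element whitelist, largest component, reionize,
# neutralize, canonical tautomer)
# ---------------------------------------------------------------------------
_reionizer = None
_uncharger = None
_tautomerizer = None


def standardizers(max_tautomers):
    global _reionizer, _uncharger, _tautomerizer
    if _reionizer is None:
        _reionizer = rdMolStandardize.Reionizer()
        _uncharger = rdMolStandardize.Uncharger()
        _tautomerizer = rdMolStandardize.TautomerEnumerator()
        _tautomerizer.SetMaxTautomers(int(max_tautomers))
    return _reionizer, _uncharger, _tautomerizer


def element_symbols(mol):
    return sorted({a.GetSymbol() for a in mol.GetAtoms()})


def largest_component(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return frags[0]
    # most heavy atoms, then higher MW, then smallest canonical string
    key = [(-f.GetNumHeavyAtoms(), -Descriptors.MolWt(f), Chem.MolToSmiles(f))
           for f in frags]
    return frags[min(range(len(frags)), key=lambda i: key[i])]


def standardize_one(smi, element_stage="pre_split", max_tautomers=1000):
    m = Chem.MolFromSmiles(smi)
    if m is None:
        return {"status": "rejected", "reason": "parse_error",
                "canonical": None, "tautomer_fallback": False}
    reion, unch, taut = standardizers(max_tautomers)
    if element_stage == "pre_split":
        if not set(element_symbols(m)) <= ELEMENT_WHITELIST:
            return {"status": "rejected", "reason": "element_violation",
                    "canonical": None, "tautomer_fallback": False}
    m = largest_component(m)
    if element_stage == "post_split":
        if not set(element_symbols(m)) <= ELEMENT_WHITELIST:
            return {"status": "rejected", "reason": "element_violation",
                    "canonical": None, "tautomer_fallback": False}
    try:
        m = reion.reionize(m)
        m = unch.uncharge(m)
    except Exception:
        return {"status": "rejected", "reason": "standardization_error",
                "canonical": None, "tautomer_fallback": False}
    fallback = False
    try:
        mt = taut.Canonicalize(m)
    except Exception:
        mt, fallback = m, True
    return {"status": "standardized", "reason": None,
            "canonical": Chem.MolToSmiles(mt), "tautomer_fallback": fallback}


# ---------------------------------------------------------------------------
# Descriptors: six RO3 properties + 18 constitutional/complexity descriptors
# ---------------------------------------------------------------------------
def descriptor_row(mol):
    atoms = mol.GetAtoms()
    n_heavy = mol.GetNumHeavyAtoms()
    n_c = sum(1 for a in atoms if a.GetAtomicNum() == 6)
    n_n = sum(1 for a in atoms if a.GetAtomicNum() == 7)
    n_o = sum(1 for a in atoms if a.GetAtomicNum() == 8)
    chiral = Chem.FindMolChiralCenters(mol, includeUnassigned=True,
                                       useLegacyImplementation=False)
    chiral_c = sum(1 for idx, _ in chiral
                   if mol.GetAtomWithIdx(idx).GetAtomicNum() == 6)
    return {
        "mw": Descriptors.MolWt(mol),
        "rb": rdMolDescriptors.CalcNumRotatableBonds(mol),
        "tpsa": Descriptors.TPSA(mol),
        "logp": Crippen.MolLogP(mol),
        "hba": Lipinski.NOCount(mol),
        "hbd": Lipinski.NHOHCount(mol),
        "n_C": n_c, "n_O": n_o, "n_N": n_n,
        "frac_C": n_c / n_heavy if n_heavy else 0.0,
        "frac_O": n_o / n_heavy if n_heavy else 0.0,
        "frac_N": n_n / n_heavy if n_heavy else 0.0,
        "frac_sp3_C": rdMolDescriptors.CalcFractionCSP3(mol),
        "frac_chiral_C": chiral_c / n_c if n_c else 0.0,
        "n_heavy": n_heavy,
        "n_rings": rdMolDescriptors.CalcNumRings(mol),
        "n_aliphatic_rings": rdMolDescriptors.CalcNumAliphaticRings(mol),
        "n_aromatic_rings": rdMolDescriptors.CalcNumAromaticRings(mol),
        "n_heterocycles": rdMolDescriptors.CalcNumHeterocycles(mol),
        "n_aliphatic_heterocycles":
            rdMolDescriptors.CalcNumAliphaticHeterocycles(mol),
        "n_aromatic_heterocycles":
            rdMolDescriptors.CalcNumAromaticHeterocycles(mol),
        "n_spiro_atoms": rdMolDescriptors.CalcNumSpiroAtoms(mol),
        "n_bridgehead_atoms": rdMolDescriptors.CalcNumBridgeheadAtoms(mol),
    }


# ---------------------------------------------------------------------------
# Synthetic accessibility score (Ertl-Schuffenhauer).
#
# Independent reimplementation of the published scheme: occurrence-weighted
# mean of radius-2 circular-substructure log-frequency contributions minus
# penalties for size, stereocentres, spiro/bridgehead atoms and macrocycles,
# with the fingerprint-density (symmetry) correction, mapped onto [1, 10].
# The circular-substructure frequency table is read from the reference
# distribution shipped with the installed toolkit (no network access).
# ---------------------------------------------------------------------------
_fscores = None
_morgan_gen = None


def fragment_score_table():
    global _fscores
    if _fscores is None:
        import os.path as op
        path = op.join(RDConfig.RDContribDir, "SA_Score", "fpscores.pkl.gz")
        data = pickle.load(gzip.open(path))
        _fscores = {bit: float(row[0]) for row in data for bit in row[1:]}
    return _fscores


def sa_breakdown(mol):
    global _morgan_gen
    if _morgan_gen is None:
        _morgan_gen = rdFingerprintGenerator.GetMorganGenerator(radius=2)
    table = fragment_score_table()
    counts = _morgan_gen.GetSparseCountFingerprint(mol).GetNonzeroElements()
    total = sum(counts.values())
    frag_score = sum(table.get(bit, -4.0) * n
                     for bit, n in counts.items()) / total

    n_atoms = mol.GetNumAtoms()
    n_chiral = len(Chem.FindMolChiralCenters(mol, includeUnassigned=True))
    n_spiro = rdMolDescriptors.CalcNumSpiroAtoms(mol)
    n_bridge = rdMolDescriptors.CalcNumBridgeheadAtoms(mol)
    n_macro = sum(1 for ring in mol.GetRingInfo().AtomRings()
                  if len(ring) > 8)

    size_pen = n_atoms ** 1.005 - n_atoms
    stereo_pen = math.log10(n_chiral + 1)
    spiro_pen = math.log10(n_spiro + 1)
    bridge_pen = math.log10(n_bridge + 1)
    macro_pen = math.log10(2) if n_macro > 0 else 0.0
    # symmetry correction: repeated environments make a molecule easier
    sym_corr = (math.log(float(n_atoms) / len(counts)) * 0.5
                if n_atoms > len(counts) else 0.0)

    penalty = size_pen + stereo_pen + spiro_pen + bridge_pen + macro_pen \
        - sym_corr
    raw = frag_score - penalty

    lo, hi = -4.0, 2.5
    score = 11.0 - (raw - lo + 1.0) / (hi - lo) * 9.0
    if score > 8.0:
        score = 8.0 + math.log(score + 1.0 - 9.0)
    score = min(10.0, max(1.0, score))
    return {"fragment_score": frag_score, "size_penalty": size_pen,
            "stereo_penalty": stereo_pen, "spiro_penalty": spiro_pen,
            "bridge_penalty": bridge_pen, "macrocycle_penalty": macro_pen,
            "symmetry_correction": sym_corr, "complexity_penalty": penalty,
            "raw": raw, "score": score}


def sa_reference(mol):
    """Reference script from the installed toolkit's contrib area (oracle)."""
    import os.path as op
    sys.path.insert(0, op.join(RDConfig.RDContribDir, "SA_Score"))
    import sascorer
    return sascorer.calculateScore(mol)


# ---------------------------------------------------------------------------
# Fingerprints
# ---------------------------------------------------------------------------
def fingerprint_bits(mol, kind):
    if kind == "maccs166":
        fp = MACCSkeys.GenMACCSKeys(mol)
        # the 167-bit vector's bit 0 is unused; report 166 bits, 0-based
        return [b - 1 for b in fp.GetOnBits() if b >= 1]
    if kind in ("morgan2_1024", "morgan3_1024"):
        radius = 2 if kind == "morgan2_1024" else 3
        gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius,
                                                        fpSize=1024)
        return list(gen.GetFingerprint(mol).GetOnBits())
    raise ValueError("unknown fingerprint kind: %s" % kind)


# ---------------------------------------------------------------------------
# Bemis-Murcko scaffolds
# ---------------------------------------------------------------------------
def scaffold_row(mol):
    scaf = MurckoScaffold.GetScaffoldForMol(mol)
    if scaf is None or scaf.GetNumHeavyAtoms() == 0:
        return {"scaffold": None}
    ri = scaf.GetRingInfo()
    rings = [set(r) for r in ri.AtomRings()]
    bond_rings = [set(r) for r in ri.BondRings()]
    fused_any = False
    ortho_fused = False
    for i in range(len(rings)):
        for j in range(i + 1, len(rings)):
            if rings[i] & rings[j]:
                fused_any = True
            # ortho-fusion: exactly one shared bond (bridged systems
            # share two or more SSSR bonds, spiro systems none)
            if len(bond_rings[i] & bond_rings[j]) == 1:
                ortho_fused = True
    ring_atoms = set().union(*rings) if rings else set()
    has_ring_het = any(scaf.GetAtomWithIdx(i).GetAtomicNum() != 6
                       for i in ring_atoms)
    has_n = any(a.GetAtomicNum() == 7 for a in scaf.GetAtoms())
    return {"scaffold": Chem.MolToSmiles(scaf),
            "n_rings": ri.NumRings(),
            "has_ring_heteroatom": has_ring_het,
            "has_nitrogen": has_n,
            "fused": fused_any,
            "ortho_fused": ortho_fused}


# ---------------------------------------------------------------------------
# t-SNE embedding (scikit-learn backend)
# ---------------------------------------------------------------------------
def run_tsne(payload):
    import numpy as np
    from sklearn.manifold import TSNE
    nbits = int(payload["nbits"])
    bits = payload["bits"]
    n = len(bits)
    x = np.zeros((n, nbits), dtype=np.float64)
    for i, row in enumerate(bits):
        if row:
            x[i, np.asarray(row, dtype=int)] = 1.0
    perplexity = float(payload.get("perplexity", 40))
    max_iter = max(250, int(payload.get("n_iter", 300)))
    seed = int(payload.get("seed", 0))
    max_perp = (n - 1) / 3.0
    reduced = False
    if perplexity >= max_perp:
        perplexity = max(1.0, math.floor(max_perp))
        reduced = True
    ts = TSNE(n_components=2, perplexity=perplexity, max_iter=max_iter,
              random_state=seed, init="pca", method="exact" if n < 500
              else "barnes_hut")
    coords = ts.fit_transform(x)
    return {"coords": [[float(a), float(b)] for a, b in coords],
            "perplexity_used": perplexity, "reduced": reduced}


# ---------------------------------------------------------------------------
# command dispatch
# ---------------------------------------------------------------------------
def mols_or_none(smiles):
    return [Chem.MolFromSmiles(s) for s in smiles]


def main(argv):
    cmd, infile, outfile = argv[1], argv[2], argv[3]
    with open(infile) as fh:
        payload = json.load(fh)
    smiles = payload.get("smiles", [])
    opts = payload.get("options", {}) or {}
    out = None

    if cmd == "parse":
        res = []
        for s in smiles:
            m = Chem.MolFromSmiles(s)
            res.append({"ok": m is not None,
                        "canonical": Chem.MolToSmiles(m) if m else None})
        out = res
    elif cmd == "elements":
        res = []
        for m in mols_or_none(smiles):
            res.append(None if m is None else element_symbols(m))
        out = res
    elif cmd == "standardize":
        stage = opts.get("element_stage", "pre_split")
        maxt = opts.get("max_tautomers", 1000)
        out = [standardize_one(s, stage, maxt) for s in smiles]
    elif cmd == "descriptors":
        res = []
        for m in mols_or_none(smiles):
            res.append(None if m is None else descriptor_row(m))
        out = res
    elif cmd == "recap":
        rng = None
        if opts.get("order_seed") is not None:
            import random
            rng = random.Random(int(opts["order_seed"]))
        res = []
        for m in mols_or_none(smiles):
            res.append(None if m is None else recap_leaves(m, rng))
        out = res
    elif cmd == "recap_bonds":
        res = []
        for m in mols_or_none(smiles):
            if m is None:
                res.append(None)
                continue
            rows = []
            for bi, rule in cleavable_bonds(m):
                b = m.GetBondWithIdx(bi)
                rows.append({"bond": bi, "a1": b.GetBeginAtomIdx(),
                             "a2": b.GetEndAtomIdx(), "rule": rule})
            res.append(rows)
        out = res
    elif cmd == "sascore":
        res = []
        for m in mols_or_none(smiles):
            res.append(None if m is None else sa_breakdown(m))
        out = res
    elif cmd == "sascore_ref":
        res = []
        for m in mols_or_none(smiles):
            res.append(None if m is None else {"score": sa_reference(m)})
        out = res
    elif cmd == "fingerprints":
        kind = opts["kind"]
        res = []
        for m in mols_or_none(smiles):
            res.append(None if m is None else fingerprint_bits(m, kind))
        out = {"bits": res,
               "nbits": 166 if kind == "maccs166" else 1024}
    elif cmd == "scaffolds":
        res = []
        for m in mols_or_none(smiles):
            res.append(None if m is None else scaffold_row(m))
        out = res
    elif cmd == "sdf_read":
        res = []
        suppl = Chem.SDMolSupplier(opts["path"], sanitize=True)
        for i, m in enumerate(suppl):
            if m is None:
                res.append({"id": "mol%05d" % (i + 1), "ok": False,
                            "smiles": None})
            else:
                name = m.GetProp("_Name") if m.HasProp("_Name") else ""
                res.append({"id": name or "mol%05d" % (i + 1), "ok": True,
                            "smiles": Chem.MolToSmiles(m)})
        out = res
    elif cmd == "sdf_write":
        w = Chem.SDWriter(opts["path"])
        ids = opts.get("ids") or ["mol%05d" % (i + 1)
                                  for i in range(len(smiles))]
        for s, name in zip(smiles, ids):
            m = Chem.MolFromSmiles(s)
            m.SetProp("_Name", str(name))
            w.write(m)
        w.close()
        out = {"n": len(smiles)}
    elif cmd == "tsne":
        out = run_tsne(payload)
    elif cmd == "recap_rules":
        out = [{"name": n, "pattern": s} for n, s in RECAP_RULES]
    else:
        raise SystemExit("unknown command: %s" % cmd)

    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv)
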