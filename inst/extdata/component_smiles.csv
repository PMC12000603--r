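role,pool,smiles,name
olefin,main,C=Cc1ccccc1,styrene
olefin,main,CC(=C)c1ccccc1,alpha-methylstyrene
olefin,main,C=CC(=O)OC,methyl acrylate
olefin,main,COC(=O)C=C(C)C,methyl 3-methylbut-2-enoate
olefin,main,CC(=O)NC(=C)c1ccccc1,N-(1-phenylvinyl)acetamide
olefin,main,COC(=O)C(=Cc1ccccc1)NC(C)=O,methyl alpha-acetamidocinnamate
olefin,main,C=CCc1ccccc1,allylbenzene
olefin,main,CC=Cc1ccccc1,beta-methylstyrene
olefin,main,C=C(C)C(=O)OC,methyl methacrylate
olefin,main,OCC=Cc1ccccc1,cinnamyl alcohol
olefin,main,OC(=O)C=C(C)C,3-methylbut-2-enoic acid
olefin,main,C=C1CCCCC1,methylenecyclohexane
olefin,main,C=CC1CCCCC1,vinylcyclohexane
olefin,main,COc1ccc(C=C)cc1,4-methoxystyrene
olefin,main,Clc1ccc(C=C)cc1,4-chlorostyrene
olefin,main,CC(=C)OC(C)=O,isopropenyl acetate
olefin,main,N#CC=Cc1ccccc1,cinnamonitrile
olefin,main,CC(=O)C=Cc1ccccc1,benzalacetone
olefin,main,C=C(c1ccccc1)c1ccccc1,"1,1-diphenylethylene"
olefin,main,CCOC(=O)C=Cc1ccccc1,ethyl cinnamate
olefin,heldout,C=CCCCC,1-hexene
olefin,heldout,CC(C)=CC(C)C,"2,4-dimethyl-2-pentene"
olefin,heldout,C=Cc1cccs1,2-vinylthiophene
olefin,heldout,C=CC(=O)N(C)C,"N,N-dimethylacrylamide"
olefin,heldout,C=Cc1ccc(F)cc1,4-fluorostyrene
olefin,heldout,CC(=C)C#N,methacrylonitrile
olefin,heldout,C=CCOC(C)=O,allyl acetate
olefin,heldout,C=CC(=O)c1ccccc1,phenyl vinyl ketone
ligand,main,c1ccc(P(c2ccccc2)c2ccccc2)cc1,triphenylphosphine
ligand,main,CC(C)P(C(C)C)C(C)C,triisopropylphosphine
ligand,main,CCCCP(CCCC)CCCC,tributylphosphine
ligand,main,C1CCC(P(C2CCCCC2)C2CCCCC2)CC1,tricyclohexylphosphine
ligand,main,COc1ccccc1P(c1ccccc1OC)c1ccccc1OC,tris(2-methoxyphenyl)phosphine
ligand,main,Cc1ccccc1P(c1ccccc1C)c1ccccc1C,tri(o-tolyl)phosphine
ligand,main,c1ccc(P(c2ccccc2)CCP(c2ccccc2)c2ccccc2)cc1,dppe
ligand,main,c1ccc(P(c2ccccc2)CCCP(c2ccccc2)c2ccccc2)cc1,dppp
ligand,main,CC(C(C)P(c1ccccc1)c1ccccc1)P(c1ccccc1)c1ccccc1,chiraphos-type diphosphine
ligand,main,COP(OC)OC,trimethyl phosphite
ligand,main,CN(C)P(N(C)C)N(C)C,tris(dimethylamino)phosphine
ligand,main,CP(C)c1ccccc1,dimethylphenylphosphine
ligand,main,c1ccc(CP(Cc2ccccc2)Cc2ccccc2)cc1,tribenzylphosphine
ligand,main,c1ccc(P(c2ccccc2)c2ccc3ccccc3c2)cc1,naphthyldiphenylphosphine
ligand,main,FC(F)(F)c1ccc(P(c2ccc(C(F)(F)F)cc2)c2ccc(C(F)(F)F)cc2)cc1,tris(4-CF3-phenyl)phosphine
ligand,heldout,CCP(CC)CC,triethylphosphine
ligand,heldout,c1ccc(P(c2ccccc2)N(C)C)cc1,aminophosphine
ligand,heldout,CCCCCCP(CCCCCC)CCCCCC,trihexylphosphine
ligand,heldout,COc1cccc(P(c2cccc(OC)c2)c2cccc(OC)c2)c1,tris(3-methoxyphenyl)phosphine
solvent,main,CO,methanol
solvent,main,CCO,ethanol
solvent,main,CC(C)O,isopropanol
solvent,main,C1CCOC1,THF
solvent,main,ClCCl,dichloromethane
solvent,main,Cc1ccccc1,toluene
solvent,main,CCOC(C)=O,ethyl acetate
solvent,main,CC#N,acetonitrile
solvent,main,C(Cl)(Cl)Cl,chloroform
solvent,main,COCCOC,DME
solvent,heldout,CC(=O)N(C)C,DMA
solvent,heldout,O1CCOCC1,"1,4-dioxane"
solvent,heldout,CCCCO,1-butanol
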