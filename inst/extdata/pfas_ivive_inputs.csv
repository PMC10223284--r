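chem_id,name,mol_weight,category,ionization_class,loec,rb,fup,clint
DTXSID3059927,Hexafluoroamylene glycol,212.09,polyfluorinated diol,ionized,2,NA,0.6770,0.00
DTXSID0059871,Pentafluoropropionamide,163.05,perfluorinated amide,ionized,20,NA,0.8089,0.00
DTXSID80310730,Octafluoroadipamide,288.10,perfluorinated amide,ionized,2,NA,0.8201,2.95
DTXSID10382147,"3-(Perfluoro-2-butyl) propane-1,2-diol",294.12,polyfluorinated diol,ionized,2,NA,0.3696,5.88
DTXSID70381090,"1H,1H,8H,8H-Perfluoro-3,6-dioxaoctane-1,8-diol",294.10,polyfluorinated diol,ionized,7,NA,0.2069,6.72
DTXSID70366226,Perfluoropentanamide,245.07,perfluorinated amide,ionized,7,NA,0.5417,14.68
DTXSID00380798,"1H,1H,11H,11H-Perfluorotetraethylene glycol",410.11,polyfluorinated diol,ionized,2,NA,0.0128,19.93
DTXSID2060965,Heptafluorobutyramide,213.06,perfluorinated amide,ionized,20,NA,0.6030,19.95
DTXSID30396867,"1H,1H,8H,8H-Perfluorooctane-1,8-diol",362.12,polyfluorinated diol,ionized,7,NA,0.0560,20.01
DTXSID30340244,"1H,1H,7H-Perfluoroheptyl 4-methylbenzenesulfonate",486.27,sulfonate ester,neutral,7,12.2968,0.0290,23.85
DTXSID60400587,Nonafluoropentanamide,263.03,perfluorinated amide,ionized,7,NA,0.1985,26.03
DTXSID1062122,4:2 Fluorotelomer alcohol,264.09,fluorotelomer alcohol,ionized,2,NA,0.1680,37.71
DTXSID50369896,"1H,1H,10H,10H-Perfluorodecane-1,10-diol",462.13,polyfluorinated diol,ionized,2,NA,0.0047,49.86
DTXSID8037708,Ammonium perfluorooctanoate (PFOA),414.07,perfluoroalkyl carboxylate,ionized,2,NA,0.0006,0.27
DTXSID8037706,Potassium perfluorooctanesulfonate (PFOS),500.13,perfluoroalkane sulfonate,ionized,7,NA,0.0040,1.81
DTXSID3038939,Perfluorooctanesulfonamide,499.15,perfluoroalkane sulfonamide,ionized,2,NA,0.0039,11.93
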