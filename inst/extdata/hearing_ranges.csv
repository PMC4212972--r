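species,scientific_name,low_hz,high_hz
bat,Unknown sp,2000,110000
cat,Felis catus,45,64000
chicken,Gallus gallus,125,2000
cow,Bos taurus,23,35000
dog,Canis lupus,67,45000
elephant,Loxodonta sp,16,12000
ferret,Mustela putorius furo,16,44000
guinea pig,Cavia porcellus,54,50000
hedgehog,Erinaceinae sp,250,45000
horse,Equus caballus,55,33500
human,Homo sapien,64,23000
house mouse,Mus musculus,2300,92000
opossum,Didelphis sp,500,64000
rabbit,Oryctolagus cuniculus,96,49000
raccoon,Procyon lotor,100,40000
rat,Rattus rattus,200,76000
sheep,Ovis aries,100,30000
cotton rat,Sigmondon hispidusi,1000,72000
brush tailed possum,Trichosurus vulpecula,,88000
fox squirrel,Sciurus niger,113,49000
northern quoll,Dasyurus hallucatus,500,40000
wood rat,Neotoma floridana,940,56000
grasshopper mouse,Onychomys leucogaster,1850,69000
kangaroo rat,Dipodomys merriami,50,62000
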