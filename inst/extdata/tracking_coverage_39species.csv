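common_name,scientific_name,n_s,n_sites,n_birds,pct_pop,pct_year_known,pct_year_unknown
Amsterdam albatross,Diomedea amsterdamensis,90,1,74,100,100,0
Antipodean albatross,Diomedea antipodensis,14864,2,211,100,100,0
Tristan albatross,Diomedea dabbenena,2218,1,52,100,100,0
Wandering albatross,Diomedea exulans,18568,5,977,100,100,0
Northern royal albatross,Diomedea sanfordi,10270,2,75,100,92,8
Short-tailed albatross,Phoebastria albatrus,2600,1,32,78,52,48
Laysan albatross,Phoebastria immutabilis,1333316,1,208,100,100,0
Waved albatross,Phoebastria irrorata,16942,1,54,100,42,58
Black-footed albatross,Phoebastria nigripes,140072,1,160,96,96,4
Sooty albatross,Phoebetria fusca,24192,4,121,100,100,0
Light-mantled albatross,Phoebetria palpebrata,41046,5,73,65,58,42
Buller's albatross,Thalassarche bulleri,65402,1,115,44,44,56
Indian yellow-nosed albatross,Thalassarche carteri,64414,2,184,87,63,37
Shy albatross,Thalassarche cauta,29368,1,143,100,83,17
Atlantic yellow-nosed albatross,Thalassarche chlororhynchos,67300,1,45,100,92,8
Gray-headed albatross,Thalassarche chrysostoma,165854,5,232,85,57,43
Chatham albatross,Thalassarche eremita,10592,1,50,100,92,8
Campbell albatross,Thalassarche impavida,43296,1,81,100,92,8
Black-browed albatross,Thalassarche melanophris,1374890,5,803,88,86,14
Salvin's albatross,Thalassarche salvini,82426,1,22,3,3,97
White-capped albatross,Thalassarche steadi,191834,1,38,100,100,0
Buller's shearwater,Ardenna bulleri,700000,1,8,100,100,0
Flesh-footed shearwater,Ardenna carneipes,148000,2,91,48,41,59
Pink-footed shearwater,Ardenna creatopus,67040,1,102,100,92,8
Great shearwater,Ardenna gravis,5000000,1,72,100,100,0
Sooty shearwater,Ardenna grisea,20000000,2,54,46,45,55
Wedge-tailed shearwater,Ardenna pacifica,5200000,4,56,58,49,51
Short-tailed shearwater,Ardenna tenuirostris,23000000,1,16,78,72,28
Cory's shearwater,Calonectris borealis,423672,4,514,98,90,10
Scopoli's shearwater,Calonectris diomedea,327250,4,228,95,80,20
Cape Verde shearwater,Calonectris edwardsii,26228,1,19,100,83,17
Streaked shearwater,Calonectris leucomelas,3000000,2,104,59,54,46
Southern giant petrel,Macronectes giganteus,95406,5,243,25,19,81
Northern giant petrel,Macronectes halli,21382,5,227,81,59,41
White-chinned petrel,Procellaria aequinoctialis,2405136,4,133,80,68,32
Gray petrel,Procellaria cinerea,151132,4,61,98,89,11
Spectacled petrel,Procellaria conspicillata,28800,1,8,100,50,50
Black petrel,Procellaria parkinsoni,3000,1,61,100,92,8
Westland petrel,Procellaria westlandica,5654,1,28,100,92,8
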