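population,acronym,order_from_north,n_females_collected,n_clutches,field_mode,pct_larviparous_clutches,pct_pueriparous_clutches,pct_mixed_clutches
CARINO,CAR,1,19,1,pueriparity,0,100,0
O VICEDO,VIC,2,1,1,pueriparity,0,100,0
MIRADOURO DE LIMO,LIM,3,5,0,na,NA,NA,NA
GARITA POINT B,GAR B,4,4,0,na,NA,NA,NA
GARITA DA HERBEIRA,GAR,5,10,0,na,NA,NA,NA
SAN ANDRES DE TEIXIDO,SAT,6,12,0,na,NA,NA,NA
CERVO,CER,7,15,2,mixed,0,0,100
CEDEIRA,CED,8,5,2,mixed,0,50,50
VALDOVINO,VAL,9,13,4,mixed,0,25,75
BELELLE,BEL,10,2,2,mixed,50,50,0
EUME,EUM,11,3,3,mixed,0,0,100
BAXOI,BAX,12,5,4,mixed,25,75,0
LAMBRE,LAM,13,6,4,mixed,0,0,100
CALLOU,CAL,14,4,4,larviparity,75,25,0
CESURAS,CES,15,4,2,larviparity,100,0,0
CHAIAN,CHA,16,9,3,larviparity,100,0,0
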