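achieng
adhiambo
adoyo
agola
ajwang
akelo
akeyo
akinyi
akoth
akumu
aluoch
anyango
aoko
apiyo
arwa
atieno
auma
awino
awiti
awuor
chebet
chepkemoi
chepkorir
cheptoo
jaber
jepchirchir
jepkosgei
juma
kadogo
kamande
kavata
kerubo
kemunto
kwamboka
makena
mghoi
moraa
mueni
mumbua
muthoni
mwende
nafula
nasimiyu
naliaka
nekesa
njeri
nyaboke
nyakio
nyambura
nyanchama
nyokabi
obiero
ochieng
odera
odhiambo
odongo
oduor
ogola
okelo
okeyo
okinyi
okoth
okumu
oluoch
omolo
omondi
onyango
ooko
opiyo
orwa
otieno
ouma
owino
owiti
owuor
wafula
wairimu
wambui
wangari
wanjala
wanjiku
wanjiru
wekesa
wycliffe
barasa
simiyu
wabwile
khisa
naswa
wanyonyi
kibet
kiprop
kipchirchir
kiplagat
kipkemboi
kimutai
kigen
jebet
chemutai
chelangat
gesare
bosibori
bonareri
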